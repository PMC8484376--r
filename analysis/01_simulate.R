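# Simulate the backcross and its pooled resequencing.
#
# Emulates the mapping design: 5 founder dams x 2 sires, 12 F1 dams, 365
# backcross progeny phenotyped as AB / WT / unclear / RB; a carrier-patterned
# pool and a non-carrier wild-type pool sequenced at 45x; and six breed pools
# of five birds at 10x sharing a 100 kb identical-by-descent segment.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

ped <- study_pedigree()
print(ped)

bc <- bc_individuals(ped)
message("phenotype margins: ",
        paste(names(table(bc$phenotype)), table(bc$phenotype),
              sep = "=", collapse = ", "))

counts <- simulate_pool_reads(ped, default_pools(), seed = SEED + 1L)
write_pool_tsv(counts, file.path(RESULTS, "pool_counts.tsv"))
write_pool_vcf(counts[counts$chrom == "chr11", ],
               file.path(RESULTS, "pool_counts_chr11.vcf"))
message("wrote ", nrow(counts), " pooled variants for pools: ",
        paste(pool_names(counts), collapse = ", "))

breeds <- simulate_breed_pools(
  6, tibble::tibble(chrom = "chr11", length_bp = 19932279),
  ibd_segment = IBD_SEGMENT, pool_size = 5, coverage = 10, seed = SEED + 2L
)
write_pool_tsv(breeds, file.path(RESULTS, "breed_pools.tsv"))
message("wrote ", nrow(breeds), " breed-pool variants (IBD segment ",
        IBD_SEGMENT$start, "-", IBD_SEGMENT$end, ")")
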