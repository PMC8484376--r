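# Informative-SNP selection and the non-recombining interval.
#
# Markers on the causal chromosome are selected from the pool counts with the
# genotyping-panel filters (alt fraction 0.4-0.6 in the patterned pool,
# < 0.2 in the wild-type pool, >= 20 reads per pool, neighbours 189-322 kb
# apart), the backcross is genotyped at them, and the maximal marker run
# with zero recombination around the perfectly associated anchor is reported.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

counts <- read_pool_tsv(file.path(RESULTS, "pool_counts.tsv"))
filter <- marker_filter(region = list(chrom = "chr11", start = 1,
                                      end = 19932279))
sel <- select_markers(counts, filter, "patterned", "wildtype", seed = SEED)
message("marker attrition: ",
        paste(names(attr(sel, "attrition")), attr(sel, "attrition"),
              sep = "=", collapse = ", "),
        "; selected ", nrow(sel), " spaced markers")
write_pool_tsv(sel[, c("chrom", "pos", "freq_a", "freq_b")],
               file.path(RESULTS, "selected_markers.tsv"))

# genotype the pedigree at the panel plus the causal locus (deterministic
# re-simulation; see 00_config.R)
ped <- study_pedigree()
panel <- dplyr::arrange(dplyr::distinct(dplyr::bind_rows(
  sel[, c("chrom", "pos")],
  tibble::tibble(chrom = "chr11", pos = 18840646)
)), pos)
gm <- build_genotype_matrix(ped, markers = panel)
write_pedigree_tsv(ped, file.path(RESULTS, "pedigree_genotypes.tsv"),
                   markers = panel)

iv <- find_nonrecombining_interval(gm,
                                   carriers = bc_individuals(ped)$causal_carrier)
print(iv)
write_interval_bed(iv, file.path(RESULTS, "interval.bed"),
                   file.path(RESULTS, "interval_summary.txt"))

# pool haplotype states around the causal gene, heatmap-style
breeds <- read_pool_tsv(file.path(RESULTS, "breed_pools.tsv"))
states <- pool_state_matrix(breeds,
                            anchor = list(chrom = "chr11", start = 18840646,
                                          end = 18841590),
                            flank = 50000)
write_pool_tsv(states, file.path(RESULTS, "pool_states_causal_flank.tsv"))
ggplot2::ggsave(file.path(RESULTS, "pool_states.png"),
                plot_pool_states(states), width = 9, height = 2.5, dpi = 150)
message("classified ", nrow(states), " variants within +/-50 kb of the causal gene")
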