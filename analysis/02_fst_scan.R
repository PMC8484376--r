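# Windowed Fst genome scan: carrier-patterned pool vs wild-type pool.
#
# Per-variant pool Fst averaged in 30 kb windows, Z-transformed genome-wide,
# Bonferroni-called in the upper tail. The expectation under the cross design
# is a block of significant windows on distal chromosome 11 containing the
# causal locus, and nothing on the background chromosome.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

counts <- read_pool_tsv(file.path(RESULTS, "pool_counts.tsv"))
scan <- fst_scan(counts, "patterned", "wildtype",
                 window_bp = 30000, min_variants = 10)
write_pool_tsv(scan, file.path(RESULTS, "fst_windows.tsv"))

sig <- scan[scan$significant, ]
message(nrow(scan), " windows scanned; ", nrow(sig),
        " Bonferroni-significant, all on: ",
        paste(unique(sig$chrom), collapse = ", "))
message("significant span: ", min(sig$start), "-", max(sig$end),
        " (causal locus at chr11:18840646)")
top <- scan[which.max(scan$z), ]
message(sprintf("top window %s:%d-%d, mean Fst %.3f, z = %.2f",
                top$chrom, top$start, top$end, top$stat, top$z))

ggplot2::ggsave(file.path(RESULTS, "fst_manhattan.png"),
                plot_manhattan(scan), width = 9, height = 3, dpi = 150)
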