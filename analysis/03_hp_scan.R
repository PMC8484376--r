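# Pooled-heterozygosity (Z_Hp) scan across the six breed pools.
#
# Major/minor read counts are summed across breeds per variant, Hp computed
# per 30 kb window, Z-transformed, and screened in the lower tail with both
# the Bonferroni call and the conventional fixed cutoff Z <= -4.70. The
# planted 100 kb shared IBD segment should surface as the heterozygosity
# minimum.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))

breeds <- read_pool_tsv(file.path(RESULTS, "breed_pools.tsv"))
scan <- hp_scan(breeds, window_bp = 30000, min_variants = 10)
write_pool_tsv(scan, file.path(RESULTS, "hp_windows.tsv"))

low <- scan[which.min(scan$z), ]
message(sprintf("minimum Z_Hp window %s:%d-%d, Hp = %.3f, z = %.2f",
                low$chrom, low$start, low$end, low$stat, low$z))
message("planted IBD segment: ", IBD_SEGMENT$start, "-", IBD_SEGMENT$end,
        "; fixed-cutoff (z <= -4.70) windows: ",
        sum(scan$significant_fixed))

ggplot2::ggsave(file.path(RESULTS, "hp_manhattan.png"),
                plot_manhattan(scan, cutoff = -4.70),
                width = 9, height = 3, dpi = 150)
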