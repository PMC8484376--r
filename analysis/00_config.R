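# Shared study configuration for the analysis scripts.
#
# Everything downstream is reproducible from (config, SEED): scripts that
# need the full pedigree haplotypes re-simulate deterministically rather
# than serializing them.

suppressPackageStartupMessages(library(poolcross))

SEED <- 17
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

study_config <- function() cross_config(n_backcross = 365)

# line-diagnostic variants every 2.5 kb so each 30 kb window holds ~12
MARKER_SPACING <- 2500

study_pedigree <- function() {
  cfg <- study_config()
  simulate_cross(cfg, markers = marker_map_for(cfg, MARKER_SPACING),
                 seed = SEED)
}

# the shared IBD segment planted for the breed-pool heterozygosity scan
IBD_SEGMENT <- list(chrom = "chr11", start = 18700001, end = 18800000)
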