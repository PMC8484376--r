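# Small fixtures shared across tests; everything is generated in code.

# one-chromosome cross at desk scale
small_config <- function(length_bp = 20e6, rate = 4, n_bc = 200,
                         causal_pos = 10e6, modifier_pos = 15e6,
                         cold_region = NULL, td = 0.5) {
  cross_config(
    n_backcross = n_bc,
    chromosomes = tibble::tibble(chrom = "chrS", length_bp = length_bp,
                                 rate_cm_mb = rate),
    causal_locus = list(chrom = "chrS", pos = causal_pos),
    modifier_locus = list(chrom = "chrS", pos = modifier_pos),
    cold_region = cold_region,
    transmission_distortion = td
  )
}

# counts table built directly from per-pool (ref, alt) pairs
counts_table <- function(pos, a_ref, a_alt, b_ref, b_alt, chrom = "chrS") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = "A", alt = "C",
    poolA_ref = a_ref, poolA_alt = a_alt,
    poolB_ref = b_ref, poolB_alt = b_alt
  )
}

# brute-force window means: double loop over (window, variant)
oracle_window_means <- function(df, value, window_bp, step_bp, min_variants) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    sub <- df[df$chrom == ch & !is.na(df[[value]]), ]
    starts <- seq(0, max(sub$pos) - 1, by = step_bp)
    for (s in starts) {
      inside <- sub$pos > s & sub$pos <= s + window_bp
      if (sum(inside) >= min_variants) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = s, end = s + window_bp,
          n_variants = sum(inside), stat = mean(sub[[value]][inside])
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
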