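#' Per-variant pool Fst
#'
#' Frequency-based fixation index between two pools,
#' Fst = (pi_between - pi_within) / pi_between, with
#' pi_within = (2 p1 q1 + 2 p2 q2) / 2 the mean within-pool expected
#' heterozygosity and pi_between = p1 q2 + p2 q1, where p_i is the alt-read
#' fraction of pool i. Variants with zero depth in either pool, or with
#' pi_between = 0 (identical fixed pools), are flagged `undefined` and are
#' excluded from downstream window means.
#'
#' @param counts tibble with `chrom`, `pos` and `<pool>_ref`/`<pool>_alt`
#'   columns (see [simulate_pool_reads()]).
#' @param pool_a,pool_b pool names.
#' @return tibble `chrom`, `pos`, `p1`, `p2`, `pi_within`, `pi_between`,
#'   `fst`, `undefined`.
#' @export
variant_fst <- function(counts, pool_a, pool_b) {
  for (p in c(pool_a, pool_b)) {
    if (!paste0(p, "_ref") %in% names(counts)) {
      stop("unknown pool name '", p, "'", call. = FALSE)
    }
  }
  ra <- counts[[paste0(pool_a, "_ref")]]; aa <- counts[[paste0(pool_a, "_alt")]]
  rb <- counts[[paste0(pool_b, "_ref")]]; ab <- counts[[paste0(pool_b, "_alt")]]
  da <- ra + aa; db <- rb + ab
  p1 <- ifelse(da > 0, aa / da, NA_real_)
  p2 <- ifelse(db > 0, ab / db, NA_real_)
  q1 <- 1 - p1; q2 <- 1 - p2
  pi_within <- (2 * p1 * q1 + 2 * p2 * q2) / 2
  pi_between <- p1 * q2 + p2 * q1
  undefined <- is.na(p1) | is.na(p2) | pi_between == 0
  fst <- ifelse(undefined, NA_real_, (pi_between - pi_within) / pi_between)
  tibble::tibble(
    chrom = counts$chrom, pos = counts$pos,
    p1 = p1, p2 = p2, pi_within = pi_within, pi_between = pi_between,
    fst = fst, undefined = undefined
  )
}

#' Windowed Fst genome scan
#'
#' Composes [variant_fst()], [window_scan()] (mean Fst per window) and
#' [zscore_windows()] in the upper tail: high-Fst windows are the
#' differentiation signal between the phenotype pools.
#'
#' @inheritParams variant_fst
#' @inheritParams window_scan
#' @param alpha family-wise significance level for the Bonferroni call.
#' @return window tibble with `stat` (mean Fst), `z`, `p_bonferroni`,
#'   `significant`.
#' @export
fst_scan <- function(counts, pool_a, pool_b, window_bp = 30000,
                     step_bp = window_bp, min_variants = 10, alpha = 0.05) {
  per_variant <- variant_fst(counts, pool_a, pool_b)
  ok <- dplyr::filter(per_variant, !.data$undefined)
  windows <- window_scan(ok, value = "fst", window_bp = window_bp,
                         step_bp = step_bp, min_variants = min_variants)
  zscore_windows(windows, alpha = alpha, tail = "upper")
}
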