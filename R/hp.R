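#' Per-variant major/minor read counts across breed pools
#'
#' Sums ref and alt reads over all pools per variant; the larger sum is the
#' major-allele count nMAJ and the smaller the minor-allele count nMIN
#' (ties broken toward ref = major). Zero-depth variants are dropped.
#'
#' @param counts multi-pool counts tibble.
#' @param pools pool names to include; default all.
#' @return tibble `chrom`, `pos`, `nmaj`, `nmin`.
#' @export
major_minor_counts <- function(counts, pools = pool_names(counts)) {
  ref <- rowSums(as.matrix(counts[paste0(pools, "_ref")]))
  alt <- rowSums(as.matrix(counts[paste0(pools, "_alt")]))
  keep <- ref + alt > 0
  tibble::tibble(
    chrom = counts$chrom[keep], pos = counts$pos[keep],
    nmaj = pmax(ref, alt)[keep],
    nmin = pmin(ref, alt)[keep]
  )
}

#' Windowed pooled heterozygosity Hp
#'
#' For each window, sums the per-variant major and minor allele read counts
#' (taken across all breed pools) and computes
#' Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2, a read-count
#' heterozygosity bounded in [0, 0.5] that attains 0.5 only at perfectly
#' balanced counts and 0 when every variant in the window is monomorphic.
#' `literal_numerator = TRUE` instead evaluates 2 * sum(nMIN) / (sum)^2, an
#' alternative (unbounded-scale) numerator kept for comparison.
#'
#' @inheritParams major_minor_counts
#' @inheritParams window_scan
#' @param literal_numerator use the 2*sum(nMIN) numerator variant.
#' @return tibble `chrom`, `start`, `end`, `n_variants`, `sum_nmaj`,
#'   `sum_nmin`, `stat` (Hp).
#' @export
hp_windows <- function(counts, pools = pool_names(counts), window_bp = 30000,
                       step_bp = window_bp, min_variants = 10,
                       literal_numerator = FALSE) {
  mm <- major_minor_counts(counts, pools)
  if (nrow(mm) == 0) stop("no variants with coverage", call. = FALSE)
  nmaj <- window_scan(mm, "nmaj", window_bp, step_bp, min_variants)
  nmin <- window_scan(mm, "nmin", window_bp, step_bp, min_variants)
  sum_nmaj <- nmaj$stat * nmaj$n_variants
  sum_nmin <- nmin$stat * nmin$n_variants
  tot <- sum_nmaj + sum_nmin
  hp <- if (literal_numerator) 2 * sum_nmin / tot^2 else
    2 * sum_nmaj * sum_nmin / tot^2
  tibble::tibble(
    chrom = nmaj$chrom, start = nmaj$start, end = nmaj$end,
    n_variants = nmaj$n_variants,
    sum_nmaj = sum_nmaj, sum_nmin = sum_nmin, stat = hp
  )
}

#' Pooled-heterozygosity genome scan (Z_Hp)
#'
#' Composes [hp_windows()] with [zscore_windows()] in the lower tail:
#' strongly negative Z_Hp marks windows with less heterozygosity than
#' expected, candidate identical-by-descent or swept regions. Both the
#' Bonferroni call and the conventional fixed cutoff (z <= -4.70) are
#' reported.
#'
#' @inheritParams hp_windows
#' @inheritParams zscore_windows
#' @return window tibble with `z`, `p_bonferroni`, `significant`,
#'   `significant_fixed`.
#' @export
hp_scan <- function(counts, pools = pool_names(counts), window_bp = 30000,
                    step_bp = window_bp, min_variants = 10, alpha = 0.05,
                    fixed_cutoff = -4.70, literal_numerator = FALSE) {
  if (length(pools) < 2) stop("need at least two breed pools", call. = FALSE)
  windows <- hp_windows(counts, pools, window_bp, step_bp, min_variants,
                        literal_numerator)
  zscore_windows(windows, alpha = alpha, tail = "lower",
                 fixed_cutoff = fixed_cutoff)
}
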