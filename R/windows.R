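#' Sliding-window mean of a per-variant statistic
#'
#' Averages a per-variant statistic over fixed windows laid on a deterministic
#' grid anchored at each chromosome's origin: window starts are multiples of
#' `step_bp` (0-based half-open coordinates), each window covering
#' `(start, start + window_bp]` in 1-based variant positions. Windows with
#' fewer than `min_variants` variants are dropped. The default step equals the
#' window, giving non-overlapping windows so the Bonferroni denominator is the
#' number of tested windows.
#'
#' @param values tibble with `chrom`, `pos` and the statistic column, sorted
#'   or not (sorted internally); `NA` statistics are dropped.
#' @param value name of the statistic column.
#' @param window_bp window size in bp (> 0).
#' @param step_bp distance between window starts (> 0); `< window_bp` slides.
#' @param min_variants minimum variants for a window to be retained.
#' @return tibble `chrom`, `start`, `end` (0-based half-open), `n_variants`,
#'   `stat`.
#' @export
window_scan <- function(values, value = "fst", window_bp = 30000,
                        step_bp = window_bp, min_variants = 10) {
  if (window_bp <= 0 || step_bp <= 0) {
    stop("window_bp and step_bp must be positive", call. = FALSE)
  }
  stopifnot(value %in% names(values))
  values <- dplyr::arrange(tibble::as_tibble(values), .data$chrom, .data$pos)
  values <- values[!is.na(values[[value]]), , drop = FALSE]
  per_chrom <- lapply(split(values, values$chrom), function(df) {
    pos <- df$pos
    v <- df[[value]]
    cum <- c(0, cumsum(v))
    max_start <- (max(pos) - 1) %/% step_bp * step_bp
    starts <- seq(0, max_start, by = step_bp)
    # variants in (start, start + window]: prefix sums over sorted positions
    lo <- findInterval(starts, pos)        # count of pos <= start
    hi <- findInterval(starts + window_bp, pos)
    n <- hi - lo
    keep <- n >= max(1, min_variants)
    tibble::tibble(
      chrom = df$chrom[1],
      start = starts[keep], end = starts[keep] + window_bp,
      n_variants = n[keep],
      stat = (cum[hi + 1] - cum[lo + 1])[keep] / n[keep]
    )
  })
  dplyr::bind_rows(per_chrom)
}

#' Z-transform windows and apply Bonferroni-corrected calls
#'
#' Standardizes the window statistic genome-wide, z = (stat - mean) / sd
#' (sample sd, denominator n - 1), computes a one-tailed normal p in the
#' requested tail, and flags windows with p x (number of retained windows)
#' below `alpha`. In the lower tail a fixed cutoff (default z <= -4.70, the
#' conventional pooled-heterozygosity rule) is additionally reported as
#' `significant_fixed`.
#'
#' @param windows output of [window_scan()] (or any tibble with `stat`).
#' @param alpha family-wise level for the Bonferroni call.
#' @param tail `"upper"` (differentiation scans) or `"lower"` (heterozygosity
#'   deficits).
#' @param fixed_cutoff fixed z threshold reported alongside the Bonferroni
#'   call when `tail = "lower"`.
#' @return input with `z`, `p`, `p_bonferroni`, `significant` (and
#'   `significant_fixed` for the lower tail) appended.
#' @export
zscore_windows <- function(windows, alpha = 0.05,
                           tail = c("upper", "lower"), fixed_cutoff = -4.70) {
  tail <- match.arg(tail)
  if (nrow(windows) < 2) stop("need at least two retained windows", call. = FALSE)
  mu <- mean(windows$stat)
  sigma <- sd(windows$stat)
  if (sigma == 0) stop("window statistic has zero variance", call. = FALSE)
  z <- (windows$stat - mu) / sigma
  p <- if (tail == "upper") pnorm(z, lower.tail = FALSE) else pnorm(z)
  out <- windows
  out$z <- z
  out$p <- p
  out$p_bonferroni <- pmin(1, p * nrow(windows))
  out$significant <- p * nrow(windows) < alpha
  if (tail == "lower") out$significant_fixed <- z <= fixed_cutoff
  out
}
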