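#' Informative-SNP selection filter
#'
#' The hard filters used to pick genotyping markers from pooled resequencing:
#' a target region, a minimum read depth per pool, and either a frequency
#' window (alt fraction 0.4-0.6 in the case pool and < 0.2 in the control
#' pool) or, in `alt_mode`, a minimum per-variant Fst; plus the target range
#' for the spacing between retained neighbours (189-322 kb by default).
#'
#' @param region `list(chrom =, start =, end =)`, 1-based inclusive.
#' @param freq_range_pool_a inclusive alt-fraction window for the case pool.
#' @param freq_max_pool_b exclusive alt-fraction ceiling for the control pool.
#' @param min_depth minimum reads per pool at the variant.
#' @param spacing_range target gap between neighbouring retained markers (bp).
#' @param min_fst if not `NULL`, replaces the frequency filters by a
#'   per-variant Fst floor (alt mode, e.g. 0.35).
#' @return object of class `marker_filter`.
#' @export
marker_filter <- function(region,
                          freq_range_pool_a = c(0.4, 0.6),
                          freq_max_pool_b = 0.2,
                          min_depth = 20,
                          spacing_range = c(189000, 322000),
                          min_fst = NULL) {
  stopifnot(
    all(c("chrom", "start", "end") %in% names(region)),
    region$start <= region$end,
    freq_range_pool_a[1] >= 0, freq_range_pool_a[2] <= 1,
    freq_range_pool_a[1] <= freq_range_pool_a[2],
    freq_max_pool_b >= 0, freq_max_pool_b <= 1,
    spacing_range[1] <= spacing_range[2], min_depth >= 0
  )
  structure(list(region = region, freq_range_pool_a = freq_range_pool_a,
                 freq_max_pool_b = freq_max_pool_b, min_depth = min_depth,
                 spacing_range = spacing_range, min_fst = min_fst),
            class = "marker_filter")
}

#' Select spaced informative markers from pool counts
#'
#' Applies the hard filters of a [marker_filter()] (region, per-pool depth,
#' then the frequency window or the Fst floor), and thins the survivors
#' left-to-right: starting from the leftmost candidate, the next marker is
#' drawn at random (seeded) among candidates whose gap from the current one
#' falls inside `spacing_range`; when none exists, the nearest candidate
#' beyond the range is taken and the oversized gap is recorded.
#'
#' @inheritParams variant_fst
#' @param filter a [marker_filter()].
#' @param seed integer seed for the random thinning.
#' @return tibble of selected markers (`chrom`, `pos`, `freq_a`, `freq_b`)
#'   with attributes `attrition` (named counts surviving each filter) and
#'   `oversized_gaps` (count of tolerated out-of-range gaps).
#' @export
select_markers <- function(counts, filter, pool_a, pool_b, seed = 1) {
  stopifnot(inherits(filter, "marker_filter"))
  ra <- counts[[paste0(pool_a, "_ref")]]; aa <- counts[[paste0(pool_a, "_alt")]]
  rb <- counts[[paste0(pool_b, "_ref")]]; ab <- counts[[paste0(pool_b, "_alt")]]
  if (is.null(ra) || is.null(rb)) stop("unknown pool name", call. = FALSE)

  reg <- filter$region
  in_region <- counts$chrom == reg$chrom &
    counts$pos >= reg$start & counts$pos <= reg$end
  depth_ok <- in_region & (ra + aa) >= filter$min_depth &
    (rb + ab) >= filter$min_depth
  fa <- aa / (ra + aa)
  fb <- ab / (rb + ab)
  if (is.null(filter$min_fst)) {
    freq_ok <- depth_ok &
      fa >= filter$freq_range_pool_a[1] & fa <= filter$freq_range_pool_a[2] &
      fb < filter$freq_max_pool_b
  } else {
    fst <- variant_fst(counts, pool_a, pool_b)$fst
    freq_ok <- depth_ok & !is.na(fst) & fst > filter$min_fst
  }
  attrition <- c(total = nrow(counts), region = sum(in_region),
                 depth = sum(depth_ok), frequency = sum(freq_ok, na.rm = TRUE))
  cand <- counts[which(freq_ok), , drop = FALSE]
  cand$freq_a <- fa[which(freq_ok)]
  cand$freq_b <- fb[which(freq_ok)]
  if (nrow(cand) == 0) {
    stop("no variants pass the hard filters (",
         paste(names(attrition), attrition, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  cand <- dplyr::arrange(cand, .data$pos)

  withr::with_seed(seed, {
    picked <- 1L
    oversized <- 0L
    repeat {
      cur <- picked[length(picked)]
      gaps <- cand$pos - cand$pos[cur]
      in_range <- which(gaps >= filter$spacing_range[1] &
                          gaps <= filter$spacing_range[2])
      if (length(in_range) > 0) {
        nxt <- if (length(in_range) == 1) in_range else sample(in_range, 1)
      } else {
        beyond <- which(gaps > filter$spacing_range[2])
        if (length(beyond) == 0) break
        nxt <- beyond[1]
        oversized <- oversized + 1L
      }
      picked <- c(picked, nxt)
    }
    out <- cand[picked, ]
    attr(out, "attrition") <- attrition
    attr(out, "oversized_gaps") <- oversized
    out
  })
}
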