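GM_CODES <- c("HOM_WT", "HET", "HOM_FAY", "MISSING")

#' Genotype matrix of backcross progeny at line-diagnostic markers
#'
#' Codes each backcross genotype by its count of founder-line-A
#' (Fayoumi-derived) alleles: 0 = `HOM_WT` (both alleles from the wild-type
#' line), 1 = `HET`, 2 = `HOM_FAY`; unknown genotypes are `MISSING`. Built
#' either from a simulated pedigree (optionally restricted to a marker subset
#' and one chromosome) or from a raw allele-count matrix.
#'
#' @param pedigree a [simulate_cross()] result, or `NULL` when `dosage` is
#'   given directly.
#' @param markers optional tibble `chrom`, `pos` restricting the marker set;
#'   positions absent from the pedigree map are dropped with a warning.
#' @param dosage optional integer matrix (markers x individuals) of line-A
#'   allele counts in {0, 1, 2, NA}, with a parallel `marker_table`.
#' @param marker_table tibble `chrom`, `pos` describing `dosage` rows.
#' @param missing_rate fraction of cells masked to `MISSING` at random
#'   (seeded), emulating genotyping dropout.
#' @param seed seed for the missingness mask.
#' @return object of class `genotype_matrix`: `markers`, `individuals`
#'   (with phenotype labels when available), and `codes`, a character matrix
#'   over the four codes.
#' @export
build_genotype_matrix <- function(pedigree = NULL, markers = NULL,
                                  dosage = NULL, marker_table = NULL,
                                  missing_rate = 0, seed = 1) {
  if (is.null(dosage)) {
    stopifnot(inherits(pedigree, "pedigree"))
    bc <- bc_individuals(pedigree)
    cols <- match(bc$id, colnames(pedigree$hap_m))
    marker_table <- pedigree$markers
    rows <- seq_len(nrow(marker_table))
    if (!is.null(markers)) {
      want <- paste(markers$chrom, markers$pos)
      have <- paste(marker_table$chrom, marker_table$pos)
      rows <- match(want, have)
      if (anyNA(rows)) {
        warning(sum(is.na(rows)), " requested markers are not on the pedigree map")
        rows <- rows[!is.na(rows)]
      }
      marker_table <- marker_table[rows, ]
    }
    dosage <- pedigree$hap_m[rows, cols, drop = FALSE] +
      pedigree$hap_p[rows, cols, drop = FALSE]
    individuals <- bc
  } else {
    stopifnot(!is.null(marker_table), nrow(marker_table) == nrow(dosage))
    individuals <- tibble::tibble(id = colnames(dosage))
  }
  codes <- matrix(GM_CODES[ifelse(is.na(dosage), 4L, dosage + 1L)],
                  nrow = nrow(dosage),
                  dimnames = list(NULL, colnames(dosage)))
  if (missing_rate > 0) {
    withr::with_seed(seed, {
      mask <- runif(length(codes)) < missing_rate
      codes[mask] <- "MISSING"
    })
  }
  structure(
    list(markers = tibble::as_tibble(marker_table), individuals = individuals,
         codes = codes),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$markers), " markers x ",
      ncol(x$codes), " individuals\n", sep = "")
  print(table(factor(x$codes, levels = GM_CODES)))
  invisible(x)
}

# Count code changes between adjacent markers within each individual on one
# chromosome; MISSING cells break the comparison (no event counted there).
adjacent_events <- function(codes) {
  n_mk <- nrow(codes)
  if (n_mk < 2) return(integer(0))
  events <- integer(n_mk - 1)
  for (i in seq_len(n_mk - 1)) {
    a <- codes[i, ]; b <- codes[i + 1, ]
    ok <- a != "MISSING" & b != "MISSING"
    events[i] <- sum(a[ok] != b[ok])
  }
  events
}

#' Maximal non-recombining marker interval around an anchor
#'
#' A recombination event is a change of genotype code between adjacent
#' markers within one individual. Starting from the anchor marker — by
#' default the marker whose `HET` status is perfectly associated with the
#' carrier predicate — the interval is extended in both directions while the
#' adjacent marker pair shows zero events across all individuals; the borders
#' are the first flanking markers with at least one event.
#'
#' @param gm a [build_genotype_matrix()] result restricted to one chromosome.
#' @param carriers logical vector over individuals (the carrier predicate),
#'   used to locate the anchor; ignored when `anchor_pos` is given.
#' @param anchor_pos optional 1-based bp position of the anchor marker.
#' @return list of class `nr_interval`: `chrom`, `first_marker`/`last_marker`
#'   indices, `start`/`end` bp (positions of the boundary markers),
#'   `border_start`/`border_end` (flanking recombinant marker positions, NA at
#'   chromosome ends), `n_informative_meioses`, `n_recombinants_at_borders`,
#'   and the per-gap event counts.
#' @export
find_nonrecombining_interval <- function(gm, carriers = NULL, anchor_pos = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(unique(gm$markers$chrom)) != 1) {
    stop("genotype matrix must cover a single chromosome", call. = FALSE)
  }
  n_mk <- nrow(gm$markers)
  if (is.null(anchor_pos)) {
    if (is.null(carriers)) stop("supply carriers or anchor_pos", call. = FALSE)
    conc <- apply(gm$codes, 1, function(row) {
      ok <- row != "MISSING"
      sum((row[ok] == "HET") == carriers[ok])
    })
    n_ok <- apply(gm$codes, 1, function(row) sum(row != "MISSING"))
    perfect <- which(conc == n_ok & n_ok > 0)
    if (length(perfect) == 0) {
      best <- order(conc / pmax(n_ok, 1), decreasing = TRUE)[1:min(3, n_mk)]
      stop("no marker is perfectly associated with the carrier predicate; ",
           "best candidates at ", paste(gm$markers$pos[best], collapse = ", "),
           call. = FALSE)
    }
    anchor <- perfect[1]   # leftmost on ties
  } else {
    anchor <- match(anchor_pos, gm$markers$pos)
    if (is.na(anchor)) stop("anchor position is not a marker", call. = FALSE)
  }
  events <- adjacent_events(gm$codes)
  first <- anchor
  while (first > 1 && events[first - 1] == 0) first <- first - 1
  last <- anchor
  while (last < n_mk && events[last] == 0) last <- last + 1
  structure(list(
    chrom = gm$markers$chrom[1],
    first_marker = first, last_marker = last,
    start = gm$markers$pos[first], end = gm$markers$pos[last],
    border_start = if (first > 1) gm$markers$pos[first - 1] else NA_real_,
    border_end = if (last < n_mk) gm$markers$pos[last + 1] else NA_real_,
    n_informative_meioses = ncol(gm$codes),
    n_recombinants_at_borders = c(
      if (first > 1) events[first - 1] else NA_integer_,
      if (last < n_mk) events[last] else NA_integer_
    ),
    events = events, anchor = anchor
  ), class = "nr_interval")
}

#' @export
print.nr_interval <- function(x, ...) {
  cat("<nr_interval> ", x$chrom, ":", format(x$start, big.mark = ","), "-",
      format(x$end, big.mark = ","), " (markers ", x$first_marker, "-",
      x$last_marker, "), ", x$n_informative_meioses, " meioses\n", sep = "")
  invisible(x)
}

#' Classify a pool's state at one variant
#'
#' Labels each variant, within one pool, as fixed for the reference allele,
#' fixed for the alternative allele, or segregating, from the alt-read
#' fraction against a symmetric threshold. With pools of five birds a single
#' heterozygote gives an expected alt fraction of 0.1, so the threshold is a
#' tunable trade-off. Zero-depth variants are `MISSING`. Used to render
#' heatmaps of pool haplotype state around an anchor gene.
#'
#' @param ref,alt read-count vectors for one pool.
#' @param threshold fixed/segregating boundary t: alt fraction < t is
#'   `FIXED_REF`, > 1 - t is `FIXED_ALT`, else `SEGREGATING`.
#' @return character vector of states.
#' @export
classify_pool_state <- function(ref, alt, threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 0.5)
  depth <- ref + alt
  f <- alt / depth
  dplyr::case_when(
    depth == 0 ~ "MISSING",
    f < threshold ~ "FIXED_REF",
    f > 1 - threshold ~ "FIXED_ALT",
    TRUE ~ "SEGREGATING"
  )
}

#' Pool-state matrix around an anchor region
#'
#' Applies [classify_pool_state()] to every pool for variants within `flank`
#' bp of an anchor interval (e.g. a gene), the data behind the pool-haplotype
#' heatmap.
#'
#' @param counts multi-pool counts tibble.
#' @param anchor `list(chrom =, start =, end =)` of the anchor gene.
#' @param flank bp added on each side.
#' @param pools pool names; default all.
#' @inheritParams classify_pool_state
#' @return tibble `chrom`, `pos`, then one state column per pool.
#' @export
pool_state_matrix <- function(counts, anchor, flank = 5000,
                              pools = pool_names(counts), threshold = 0.1) {
  keep <- counts$chrom == anchor$chrom &
    counts$pos >= anchor$start - flank & counts$pos <= anchor$end + flank
  sub <- counts[keep, , drop = FALSE]
  out <- tibble::tibble(chrom = sub$chrom, pos = sub$pos)
  for (p in pools) {
    out[[p]] <- classify_pool_state(sub[[paste0(p, "_ref")]],
                                    sub[[paste0(p, "_alt")]], threshold)
  }
  out
}
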