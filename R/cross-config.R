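#' Chromosome table for the default simulated genome
#'
#' Two chromosomes at roughly their real chicken lengths: chromosome 1
#' (~197 Mb, carrying the modifier locus and serving as the neutral
#' background of the genome scans) and chromosome 11 (~19.9 Mb, carrying the
#' causal locus near its distal end). Recombination defaults to the chicken
#' genome-wide average of about 4 cM/Mb.
#'
#' @param rate_cm_mb recombination rate in cM/Mb applied to every chromosome.
#' @return tibble with columns `chrom`, `length_bp`, `rate_cm_mb`.
#' @export
default_genome <- function(rate_cm_mb = 4) {
  tibble::tibble(
    chrom      = c("chr1", "chr11"),
    length_bp  = c(197e6, 19932279),
    rate_cm_mb = rate_cm_mb
  )
}

#' Configuration of the experimental backcross
#'
#' Describes the two-sire x five-dam founder cross, the twelve F1 dams, and the
#' backcross cohort, together with the loci that drive the phenotype model: a
#' fully penetrant biallelic causal locus and a linked-or-unlinked modifier.
#' An optional low-recombination (`cold_region`) segment overrides the local
#' rate, emulating the suppressed recombination observed at the distal end of
#' chromosome 11. `transmission_distortion` is the probability that a maternal
#' backcross gamete carries the founder-line allele at the causal locus
#' (0.5 = Mendelian; the preset 159/365 mimics the observed carrier deficit).
#'
#' @param n_founder_dams,n_founder_sires,n_f1_dams,n_backcross pedigree sizes.
#' @param chromosomes tibble with `chrom`, `length_bp`, `rate_cm_mb`.
#' @param causal_locus,modifier_locus lists `list(chrom =, pos =)`; positions
#'   are 1-based bp and must fall on their chromosome.
#' @param cold_region optional `list(chrom =, start =, end =, rate_cm_mb =)`.
#' @param transmission_distortion probability in (0, 1).
#' @return object of class `cross_config`.
#' @export
cross_config <- function(n_founder_dams = 5,
                         n_founder_sires = 2,
                         n_f1_dams = 12,
                         n_backcross = 365,
                         chromosomes = default_genome(),
                         causal_locus = list(chrom = "chr11", pos = 18840646),
                         modifier_locus = list(chrom = "chr1", pos = 50e6),
                         cold_region = list(chrom = "chr11", start = 18800000,
                                            end = 19932279, rate_cm_mb = 0.04),
                         transmission_distortion = 0.5) {
  stopifnot(
    n_founder_dams >= 1, n_founder_sires >= 1, n_f1_dams >= 1, n_backcross >= 1,
    all(c("chrom", "length_bp", "rate_cm_mb") %in% names(chromosomes)),
    all(chromosomes$rate_cm_mb >= 0),
    transmission_distortion > 0, transmission_distortion < 1
  )
  for (locus in list(causal_locus, modifier_locus)) {
    i <- match(locus$chrom, chromosomes$chrom)
    if (is.na(i)) {
      stop("locus chromosome '", locus$chrom, "' is not in the genome", call. = FALSE)
    }
    if (locus$pos < 1 || locus$pos > chromosomes$length_bp[i]) {
      stop("locus position ", locus$pos, " lies outside ", locus$chrom, call. = FALSE)
    }
  }
  if (!is.null(cold_region)) {
    stopifnot(cold_region$start <= cold_region$end, cold_region$rate_cm_mb >= 0)
    if (!cold_region$chrom %in% chromosomes$chrom) {
      stop("cold_region chromosome not in the genome", call. = FALSE)
    }
  }
  structure(
    list(
      n_founder_dams = n_founder_dams, n_founder_sires = n_founder_sires,
      n_f1_dams = n_f1_dams, n_backcross = n_backcross,
      chromosomes = chromosomes, causal_locus = causal_locus,
      modifier_locus = modifier_locus, cold_region = cold_region,
      transmission_distortion = transmission_distortion
    ),
    class = "cross_config"
  )
}

#' Observed transmission-ratio-distortion preset
#'
#' The backcross showed 159 causal-allele carriers out of 365 progeny instead
#' of the Mendelian 182.5; this preset reproduces that deficit.
#' @export
distorted_transmission <- function() 159 / 365

#' Phenotype model: P(category | causal genotype, modifier genotype, sex)
#'
#' A conditional probability table over the four plumage categories
#' AB (autosomal barring), WT (wild-type), UNCLEAR (irregular pattern) and
#' RB (red belly). The default model encodes the structural zeros of the
#' observed cross — no AB or UNCLEAR bird lacks the causal allele, and RB
#' occurs only in males — and completes the unprinted joint causal x modifier
#' table by letting the modifier act only among causal-allele carriers.
#'
#' @param table data.frame with columns `causal` (carrier flag), `modifier`
#'   (carrier flag), `sex` ("M"/"F"), and probability columns `AB`, `WT`,
#'   `UNCLEAR`, `RB` summing to 1 per row. All 8 combinations must be present.
#' @return object of class `phenotype_model`.
#' @export
phenotype_model <- function(table = default_phenotype_table()) {
  needed <- c("causal", "modifier", "sex", "AB", "WT", "UNCLEAR", "RB")
  stopifnot(all(needed %in% names(table)), nrow(table) == 8)
  p <- as.matrix(table[, c("AB", "WT", "UNCLEAR", "RB")])
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8)) {
    stop("phenotype probabilities must be non-negative and sum to 1 per row",
         call. = FALSE)
  }
  structure(list(table = tibble::as_tibble(table)), class = "phenotype_model")
}

#' Default phenotype probability table
#'
#' Parameterized from the observed category margins: among patterned (non-RB)
#' carriers, modifier carriers are AB rather than UNCLEAR with probability
#' 66/69 and non-carriers with probability 36/61; RB affects only carrier and
#' non-carrier males at rates 2*29/159 and 2*3/206 (RB is male-limited, so the
#' male-conditional rate is twice the overall carrier-row rate); non-carriers
#' are otherwise WT.
#'
#' @return data.frame accepted by [phenotype_model()].
#' @export
default_phenotype_table <- function() {
  rb_carrier <- 2 * 29 / 159
  rb_noncar  <- 2 * 3 / 206
  p_ab_mod   <- 66 / 69   # AB vs UNCLEAR split, modifier carriers
  p_ab_nomod <- 36 / 61   # AB vs UNCLEAR split, modifier non-carriers
  row <- function(causal, modifier, sex) {
    if (!causal) {
      rb <- if (sex == "M") rb_noncar else 0
      c(AB = 0, WT = 1 - rb, UNCLEAR = 0, RB = rb)
    } else {
      rb <- if (sex == "M") rb_carrier else 0
      ab <- if (modifier) p_ab_mod else p_ab_nomod
      c(AB = (1 - rb) * ab, WT = 0, UNCLEAR = (1 - rb) * (1 - ab), RB = rb)
    }
  }
  grid <- expand.grid(causal = c(FALSE, TRUE), modifier = c(FALSE, TRUE),
                      sex = c("F", "M"), stringsAsFactors = FALSE)
  probs <- t(mapply(row, grid$causal, grid$modifier, grid$sex))
  cbind(grid, as.data.frame(probs))
}

#' Regular marker map over a genome
#'
#' Places line-diagnostic biallelic markers at fixed spacing along each
#' chromosome; loci required by a [cross_config()] should be added with
#' `extra` so they are on the map exactly.
#'
#' @param chromosomes tibble `chrom`, `length_bp`.
#' @param spacing_bp distance between consecutive markers.
#' @param extra optional tibble `chrom`, `pos` of positions to force onto the map.
#' @return tibble `chrom`, `pos` sorted by (chrom, pos).
#' @export
marker_map <- function(chromosomes, spacing_bp = 10000, extra = NULL) {
  stopifnot(spacing_bp > 0)
  maps <- lapply(seq_len(nrow(chromosomes)), function(i) {
    tibble::tibble(
      chrom = chromosomes$chrom[i],
      pos   = seq(spacing_bp, chromosomes$length_bp[i], by = spacing_bp)
    )
  })
  out <- dplyr::bind_rows(maps)
  if (!is.null(extra)) {
    out <- dplyr::bind_rows(out, tibble::as_tibble(extra[, c("chrom", "pos")]))
  }
  dplyr::arrange(dplyr::distinct(out), .data$chrom, .data$pos)
}

#' Marker map matching a cross configuration
#'
#' Convenience wrapper: regular spacing plus the causal and modifier loci.
#' @inheritParams marker_map
#' @param config a [cross_config()].
#' @export
marker_map_for <- function(config, spacing_bp = 10000) {
  marker_map(
    config$chromosomes, spacing_bp,
    extra = tibble::tibble(
      chrom = c(config$causal_locus$chrom, config$modifier_locus$chrom),
      pos   = c(config$causal_locus$pos, config$modifier_locus$pos)
    )
  )
}
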