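#' Segregation-distortion chi-square test
#'
#' Pearson chi-square of observed class counts against an expected ratio
#' (default 1:1), the classical test for transmission-ratio distortion in a
#' backcross. No continuity correction is applied: the observed carrier
#' deficit of 159 vs 206 gives chi-square 6.05 uncorrected (5.69 with Yates).
#'
#' @param observed vector of class counts (>= 2 classes, total > 0).
#' @param expected_ratio positive weights, recycled-checked against classes.
#' @return list of class `segregation_test`: `observed`, `expected`, `chi2`,
#'   `df`, `p`.
#' @export
segregation_chisq <- function(observed, expected_ratio = rep(1, length(observed))) {
  if (length(observed) < 2) stop("need at least two classes", call. = FALSE)
  if (length(expected_ratio) != length(observed)) {
    stop("expected_ratio must match the number of classes", call. = FALSE)
  }
  if (sum(observed) <= 0) stop("total count must be positive", call. = FALSE)
  if (any(expected_ratio <= 0)) stop("expected ratio entries must be positive",
                                     call. = FALSE)
  expected <- sum(observed) * expected_ratio / sum(expected_ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p = pchisq(chi2, df, lower.tail = FALSE)),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Segregation chi-square: X2 = ", round(x$chi2, 2), ", df = ", x$df,
      ", p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Phenotype-genotype association tables
#'
#' Cross-tabulates the phenotype category against carrier status at each
#' named locus over the backcross progeny, the table used to demonstrate the
#' complete association of the patterned phenotypes with the causal allele
#' (structural zeros: no AB or UNCLEAR bird among non-carriers under the
#' default model).
#'
#' @param pedigree a [simulate_cross()] result.
#' @param loci named list; each element is the column of `bc_individuals()`
#'   holding the carrier flag (default the causal and modifier loci).
#' @return named list of contingency tables (genotype x phenotype, with
#'   totals).
#' @export
association_table <- function(pedigree,
                              loci = list(causal = "causal_carrier",
                                          modifier = "modifier_carrier")) {
  bc <- bc_individuals(pedigree)
  cats <- c("AB", "WT", "UNCLEAR", "RB")
  lapply(loci, function(col) {
    if (!col %in% names(bc)) stop("locus column '", col, "' absent", call. = FALSE)
    tab <- table(
      genotype = factor(ifelse(bc[[col]], "het_carrier", "non_carrier"),
                        levels = c("non_carrier", "het_carrier")),
      phenotype = factor(bc$phenotype, levels = cats)
    )
    stats::addmargins(tab)
  })
}

#' Two-point LOD score for a backcross
#'
#' In a backcross every progeny is one informative meiosis: the maternal
#' gamete is recombinant or not between two loci. The recombination fraction
#' is estimated as r_hat = R/N (the binomial maximum-likelihood estimate) and
#' the LOD score is the base-10 log likelihood ratio of linkage at r_hat
#' against free recombination, LOD = R log10(r_hat/0.5) +
#' (N - R) log10((1 - r_hat)/0.5), with the R = 0 limit N log10 2.
#'
#' @param carrier_a,carrier_b logical vectors: carrier status (maternal
#'   line-A allele present) at the two loci per progeny; `NA` meioses are
#'   excluded and counted.
#' @return list of class `two_point_lod`: `n` informative meioses, `r`
#'   recombinants, `r_hat`, `lod`, `n_excluded`.
#' @export
two_point_lod <- function(carrier_a, carrier_b) {
  stopifnot(length(carrier_a) == length(carrier_b))
  ok <- !is.na(carrier_a) & !is.na(carrier_b)
  n <- sum(ok)
  if (n == 0) stop("no informative meioses", call. = FALSE)
  r <- sum(xor(carrier_a[ok], carrier_b[ok]))
  r_hat <- r / n
  lod <- if (r == 0 || r == n) {
    n * log10(2)  # fully informative limit at r_hat = 0 or 1
  } else {
    r * log10(r_hat / 0.5) + (n - r) * log10((1 - r_hat) / 0.5)
  }
  structure(list(n = n, r = r, r_hat = r_hat, lod = lod,
                 n_excluded = sum(!ok)),
            class = "two_point_lod")
}

#' @export
print.two_point_lod <- function(x, ...) {
  cat("Two-point LOD: N = ", x$n, ", R = ", x$r, ", r_hat = ",
      round(x$r_hat, 4), ", LOD = ", round(x$lod, 2), "\n", sep = "")
  invisible(x)
}

#' Expected double-heterozygote fraction in a backcross
#'
#' The fraction of backcross progeny heterozygous at both of two loci carried
#' in coupling by the F1 dam is the probability that the single maternal
#' recombinant gamete transmits both founder alleles, (1 - r)/2 for
#' recombination fraction r: 50% for fully linked loci (r = 0) down to 25%
#' for unlinked loci (r = 0.5).
#'
#' @param r recombination fraction in [0, 0.5].
#' @return expected fraction in [0.25, 0.5].
#' @export
double_het_expectation <- function(r) {
  if (any(r < 0 | r > 0.5)) {
    stop("recombination fraction must lie in [0, 0.5]", call. = FALSE)
  }
  (1 - r) / 2
}
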