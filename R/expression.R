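#' Relative expression by the delta-delta-Ct method
#'
#' Each sample's target Ct is normalized against the arithmetic mean of two
#' housekeeping-gene Cts (delta Ct), then against the mean delta Ct of the
#' calibrator group (delta-delta Ct); fold change is 2^-ddCt under the
#' assumption of perfect doubling per cycle. The calibrator group's mean fold
#' change is 1 by construction. Samples missing a housekeeping Ct are dropped
#' with a warning. The group contrast p-value comes from [group_compare()]
#' on the per-sample delta Ct.
#'
#' @param samples long tibble with columns `sample`, `group`, `gene`, `ct`.
#' @param target target gene name.
#' @param hk_genes the two housekeeping gene names.
#' @param calibrator calibrator group label.
#' @return list of class `ddct_result`: per-sample tibble (`sample`, `group`,
#'   `dct`, `ddct`, `fold`) and a per-group summary (`mean_fold` — the group
#'   fold 2^-mean(ddCt), exactly 1 for the calibrator —, `sem_fold` the SEM
#'   of per-sample folds, `n`), plus `p` for the two-group contrast (NA if
#'   not two groups).
#' @export
relative_expression <- function(samples, target, hk_genes = c("EEF2", "ACTB"),
                                calibrator = "non_barred") {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(samples)),
            length(hk_genes) == 2)
  wide <- tidyr::pivot_wider(
    dplyr::filter(samples, .data$gene %in% c(target, hk_genes)),
    id_cols = c("sample", "group"), names_from = "gene", values_from = "ct"
  )
  for (g in c(target, hk_genes)) if (!g %in% names(wide)) wide[[g]] <- NA_real_
  usable <- !is.na(wide[[target]]) & !is.na(wide[[hk_genes[1]]]) &
    !is.na(wide[[hk_genes[2]]])
  if (any(!usable)) {
    warning(sum(!usable), " sample(s) dropped for missing Ct values")
    wide <- wide[usable, ]
  }
  if (!calibrator %in% wide$group) stop("no usable calibrator samples", call. = FALSE)
  dct <- wide[[target]] - (wide[[hk_genes[1]]] + wide[[hk_genes[2]]]) / 2
  ddct <- dct - mean(dct[wide$group == calibrator])
  per_sample <- tibble::tibble(sample = wide$sample, group = wide$group,
                               dct = dct, ddct = ddct, fold = 2^-ddct)
  summary <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$group),
    # group fold on the Ct (log2) scale: exactly 1 for the calibrator
    mean_fold = 2^-mean(.data$ddct),
    sem_fold = sd(.data$fold) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  groups <- unique(per_sample$group)
  p <- NA_real_
  if (length(groups) == 2 && all(table(per_sample$group) >= 2)) {
    other <- setdiff(groups, calibrator)
    # degenerate noise-free input leaves the contrast untestable (p = NA)
    p <- tryCatch(
      group_compare(per_sample$dct[per_sample$group == other],
                    per_sample$dct[per_sample$group == calibrator])$p,
      error = function(e) NA_real_
    )
  }
  structure(list(target = target, calibrator = calibrator,
                 per_sample = per_sample, summary = summary, p = p),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  other <- dplyr::filter(x$summary, .data$group != x$calibrator)
  cat(x$target, ": fold change ", round(other$mean_fold, 1), " ± ",
      round(other$sem_fold, 1), " (mean ± SEM vs ", x$calibrator,
      "), p = ", signif(x$p, 2), ", Student's t test\n", sep = "")
  invisible(x)
}

#' Classical two-sample Student's t test
#'
#' Equal-variance (pooled) two-sided t test; `welch = TRUE` switches to the
#' unequal-variance form.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use the Welch correction.
#' @return list `t`, `df`, `p`.
#' @export
group_compare <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(c(a - mean(a), b - mean(b))) == 0) {
    # degenerate constant groups: no evidence of a difference when means agree
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("zero pooled variance", call. = FALSE)
  }
  fit <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Allelic-imbalance summary and test
#'
#' Summarizes the founder-line allele fraction in heterozygotes by template
#' (cDNA vs genomic-DNA control, where a perfect 50:50 ratio is expected) and
#' tests cDNA hets against gDNA hets with a Student's t test; also reports
#' the deviation of the cDNA mean from 0.5.
#'
#' @param obs tibble with `sample`, `template` ("cDNA"/"gDNA"), `genotype`
#'   ("het"/"hom_ref"/"hom_fay"), `fraction` in [0, 1].
#' @param gene label carried through to the output.
#' @return list of class `ai_result`: per-template `summary`
#'   (`mean`, `sem`, `n`), `p` (cDNA vs gDNA het t test, NA without gDNA
#'   controls), `deviation_from_half` of the cDNA mean.
#' @export
allelic_imbalance <- function(obs, gene = "") {
  stopifnot(all(c("template", "genotype", "fraction") %in% names(obs)),
            all(obs$fraction >= 0 & obs$fraction <= 1))
  het <- dplyr::filter(obs, .data$genotype == "het")
  if (sum(het$template == "cDNA") < 2) {
    stop("need at least two cDNA heterozygote observations", call. = FALSE)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(het, .data$template),
    mean = mean(.data$fraction),
    sem = sd(.data$fraction) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  cdna <- het$fraction[het$template == "cDNA"]
  gdna <- het$fraction[het$template == "gDNA"]
  p <- NA_real_
  if (length(gdna) >= 2) {
    p <- group_compare(cdna, gdna)$p
  } else {
    warning("no gDNA heterozygote controls; test skipped")
  }
  structure(list(gene = gene, summary = summary, p = p,
                 deviation_from_half = mean(cdna) - 0.5),
            class = "ai_result")
}

#' @export
print.ai_result <- function(x, ...) {
  cdna <- dplyr::filter(x$summary, .data$template == "cDNA")
  cat(x$gene, ": founder-allele expression ", round(100 * cdna$mean, 1),
      " ± ", round(100 * cdna$sem, 2), "% (cDNA hets, mean ± SEM), ",
      "cDNA vs gDNA p = ", signif(x$p, 2), "\n", sep = "")
  invisible(x)
}

#' Simulate a qPCR Ct table with a known fold change
#'
#' Draws per-sample target and housekeeping Cts with Gaussian noise, a random
#' per-sample plate shift (which delta-delta-Ct must cancel), and a true
#' log2 fold change applied to the case group's target gene.
#'
#' @param true_fold fold change of the case group relative to the calibrator.
#' @param n_per_group samples per group.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param base_ct baseline target Ct; housekeeping genes sit near 18 and 16.
#' @param target,hk_genes,groups gene and group labels.
#' @param seed integer seed.
#' @return long tibble `sample`, `group`, `gene`, `ct`.
#' @export
simulate_ct_data <- function(true_fold = 2.3, n_per_group = 10,
                             noise_sd = 0.3, base_ct = 24, target = "MC1R",
                             hk_genes = c("EEF2", "ACTB"),
                             groups = c("barred", "non_barred"), seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in groups) {
      shift_target <- if (g == groups[1]) -log2(true_fold) else 0
      for (i in seq_len(n_per_group)) {
        id <- paste0(g, "_", i)
        plate <- rnorm(1, 0, 0.5)   # common shift across the sample's wells
        cts <- c(base_ct + shift_target, 18, 16) + plate +
          rnorm(3, 0, noise_sd)
        rows[[id]] <- tibble::tibble(sample = id, group = g,
                                     gene = c(target, hk_genes), ct = cts)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate pyrosequencing allele-fraction observations
#'
#' Heterozygote cDNA observations around a true expressed founder-allele
#' fraction and gDNA controls around 0.5, with Gaussian measurement noise.
#'
#' @param true_fraction expressed founder-allele fraction in cDNA hets.
#' @param n_cdna,n_gdna numbers of het observations per template.
#' @param noise_sd measurement noise on the fraction scale.
#' @param seed integer seed.
#' @return tibble accepted by [allelic_imbalance()].
#' @export
simulate_allele_fractions <- function(true_fraction = 0.431, n_cdna = 15,
                                      n_gdna = 15, noise_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    clamp <- function(x) pmin(1, pmax(0, x))
    tibble::tibble(
      sample = c(paste0("c", seq_len(n_cdna)), paste0("g", seq_len(n_gdna))),
      template = c(rep("cDNA", n_cdna), rep("gDNA", n_gdna)),
      genotype = "het",
      fraction = clamp(c(rnorm(n_cdna, true_fraction, noise_sd),
                         rnorm(n_gdna, 0.5, noise_sd)))
    )
  })
}
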