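#' @importFrom stats rpois rbinom runif rnorm sd pchisq pnorm pt setNames
#' @importFrom rlang .data
NULL

# Piecewise-linear genetic map for one chromosome: base rate in cM/Mb with an
# optional cold-region override. Returns physical breakpoints (bp) and the
# cumulative genetic position (cM) at each breakpoint.
genetic_map <- function(length_bp, rate_cm_mb, cold_region = NULL) {
  bp <- c(0, length_bp)
  rates <- rate_cm_mb
  if (!is.null(cold_region)) {
    s <- max(0, cold_region$start - 1)
    e <- min(length_bp, cold_region$end)
    bp <- sort(unique(c(0, s, e, length_bp)))
    rates <- vapply(seq_len(length(bp) - 1), function(i) {
      mid <- (bp[i] + bp[i + 1]) / 2
      if (mid > s && mid <= e) cold_region$rate_cm_mb else rate_cm_mb
    }, numeric(1))
  }
  seg_cm <- diff(bp) / 1e6 * rates
  list(bp = bp, cum_cm = c(0, cumsum(seg_cm)))
}

# Crossover positions (bp) of one meiosis under the Haldane model: Poisson
# number of exchanges, placed uniformly on the genetic map, no interference.
draw_crossovers <- function(gmap) {
  total_cm <- gmap$cum_cm[length(gmap$cum_cm)]
  n <- rpois(1, total_cm / 100)
  if (n == 0) return(numeric(0))
  u <- sort(runif(n, 0, total_cm))
  # invert the piecewise-linear cM -> bp map
  seg <- findInterval(u, gmap$cum_cm, rightmost.closed = TRUE)
  seg <- pmin(seg, length(gmap$bp) - 1)
  frac <- (u - gmap$cum_cm[seg]) / pmax(gmap$cum_cm[seg + 1] - gmap$cum_cm[seg], 1e-12)
  gmap$bp[seg] + frac * (gmap$bp[seg + 1] - gmap$bp[seg])
}

# Allele origin (1 = founder line A, 0 = line B) along a gamete at marker
# positions, given crossover positions and the origin of the leftmost segment.
gamete_alleles <- function(marker_pos, crossovers, start_is_a) {
  parity <- findInterval(marker_pos, crossovers) %% 2L
  as.integer(xor(start_is_a, parity == 1L))
}

#' Simulate the backcross pedigree
#'
#' Founder dams are homozygous for the line-A (Fayoumi-like) allele at every
#' marker and founder sires homozygous line-B (Leghorn-like); F1 dams are
#' uniformly heterozygous. Each backcross progeny receives one recombinant
#' maternal gamete (Haldane model, no interference; the configured cold region
#' overrides the local rate) and one non-recombinant line-B paternal gamete.
#' Transmission-ratio distortion is applied as the probability that the
#' maternal gamete carries the line-A allele at the causal locus. Phenotypes
#' are drawn from the [phenotype_model()] given causal carrier status,
#' modifier carrier status and sex. Fully reproducible from `seed`.
#'
#' @param config a [cross_config()].
#' @param model a [phenotype_model()].
#' @param markers tibble `chrom`, `pos`; must contain the causal and modifier
#'   loci exactly.
#' @param seed integer seed.
#' @return object of class `pedigree`: individual table (`id`, `sire`, `dam`,
#'   `sex`, `generation`, `phenotype`, carrier flags), marker table, maternal
#'   and paternal allele-origin matrices (markers x individuals, 1 = line A),
#'   and a per-progeny crossover log.
#' @export
simulate_cross <- function(config, model = phenotype_model(),
                           markers = marker_map_for(config), seed = 1) {
  stopifnot(inherits(config, "cross_config"), inherits(model, "phenotype_model"))
  markers <- dplyr::arrange(tibble::as_tibble(markers), .data$chrom, .data$pos)
  if (nrow(markers) == 0) stop("marker map is empty", call. = FALSE)
  key <- paste(markers$chrom, markers$pos)
  causal_idx <- match(paste(config$causal_locus$chrom, config$causal_locus$pos), key)
  modifier_idx <- match(paste(config$modifier_locus$chrom, config$modifier_locus$pos), key)
  if (is.na(causal_idx)) stop("causal locus is not on the marker map", call. = FALSE)
  if (is.na(modifier_idx)) stop("modifier locus is not on the marker map", call. = FALSE)

  chroms <- config$chromosomes
  gmaps <- lapply(seq_len(nrow(chroms)), function(i) {
    cr <- config$cold_region
    if (!is.null(cr) && cr$chrom != chroms$chrom[i]) cr <- NULL
    genetic_map(chroms$length_bp[i], chroms$rate_cm_mb[i], cr)
  })
  names(gmaps) <- chroms$chrom
  mk_rows <- split(seq_len(nrow(markers)), markers$chrom)

  withr::with_seed(seed, {
    n_p  <- config$n_founder_dams + config$n_founder_sires + 1L  # + BC sire
    n_f1 <- config$n_f1_dams
    n_bc <- config$n_backcross
    n_mk <- nrow(markers)
    n_all <- n_p + n_f1 + n_bc

    dam_ids  <- paste0("FAY_D", seq_len(config$n_founder_dams))
    sire_ids <- paste0("LEG_S", seq_len(config$n_founder_sires))
    bc_sire  <- "LEG_BC_S1"
    f1_ids   <- paste0("F1_", seq_len(n_f1))
    bc_ids   <- sprintf("BC_%03d", seq_len(n_bc))

    hap_m <- matrix(0L, n_mk, n_all)
    hap_p <- matrix(0L, n_mk, n_all)
    colnames(hap_m) <- colnames(hap_p) <- c(dam_ids, sire_ids, bc_sire, f1_ids, bc_ids)
    hap_m[, dam_ids] <- 1L
    hap_p[, dam_ids] <- 1L
    hap_m[, f1_ids] <- 1L   # maternal haplotype from a Fayoumi dam

    f1_dam  <- sample(dam_ids, n_f1, replace = TRUE)
    f1_sire <- sample(sire_ids, n_f1, replace = TRUE)
    bc_dam  <- sample(f1_ids, n_bc, replace = TRUE)

    causal_chrom <- config$causal_locus$chrom
    causal_pos   <- config$causal_locus$pos
    td <- config$transmission_distortion
    xo_log <- vector("list", n_bc)

    for (j in seq_len(n_bc)) {
      col <- n_p + n_f1 + j
      xo_all <- list()
      for (ci in seq_len(nrow(chroms))) {
        cname <- chroms$chrom[ci]
        rows <- mk_rows[[cname]]
        if (is.null(rows)) next
        xo <- draw_crossovers(gmaps[[cname]])
        if (cname == causal_chrom) {
          # fix the allele at the causal locus (Bernoulli td), then choose the
          # leftmost-segment origin consistent with the drawn crossovers
          carrier <- runif(1) < td
          parity <- findInterval(causal_pos, xo) %% 2L
          start_is_a <- xor(carrier, parity == 1L)
        } else {
          start_is_a <- runif(1) < 0.5
        }
        hap_m[rows, col] <- gamete_alleles(markers$pos[rows], xo, start_is_a)
        if (length(xo)) xo_all[[cname]] <- tibble::tibble(chrom = cname, pos = xo)
      }
      xo_log[[j]] <- if (length(xo_all)) dplyr::bind_rows(xo_all) else
        tibble::tibble(chrom = character(), pos = numeric())
    }

    sex <- c(
      rep("F", config$n_founder_dams), rep("M", config$n_founder_sires + 1L),
      rep("F", n_f1),
      sample(c("M", "F"), n_bc, replace = TRUE)
    )
    bc_cols <- n_p + n_f1 + seq_len(n_bc)
    causal_carrier <- hap_m[causal_idx, bc_cols] + hap_p[causal_idx, bc_cols] > 0
    modifier_carrier <- hap_m[modifier_idx, bc_cols] + hap_p[modifier_idx, bc_cols] > 0
    phenotype <- draw_phenotypes(model, causal_carrier, modifier_carrier,
                                 sex[bc_cols])

    individuals <- tibble::tibble(
      id = colnames(hap_m),
      sire = c(rep(NA, n_p), f1_sire, rep(bc_sire, n_bc)),
      dam = c(rep(NA, n_p), f1_dam, bc_dam),
      sex = sex,
      generation = c(rep("P", n_p), rep("F1", n_f1), rep("BC", n_bc)),
      phenotype = c(rep(NA, n_p + n_f1), phenotype),
      causal_carrier = c(rep(NA, n_p + n_f1), causal_carrier),
      modifier_carrier = c(rep(NA, n_p + n_f1), modifier_carrier)
    )
    names(xo_log) <- bc_ids

    structure(
      list(config = config, markers = markers, individuals = individuals,
           hap_m = hap_m, hap_p = hap_p, crossovers = xo_log,
           causal_idx = causal_idx, modifier_idx = modifier_idx, seed = seed),
      class = "pedigree"
    )
  })
}

draw_phenotypes <- function(model, causal, modifier, sex) {
  tab <- model$table
  cats <- c("AB", "WT", "UNCLEAR", "RB")
  vapply(seq_along(causal), function(i) {
    row <- tab[tab$causal == causal[i] & tab$modifier == modifier[i] &
                 tab$sex == sex[i], ]
    sample(cats, 1, prob = as.numeric(row[1, cats]))
  }, character(1))
}

#' @export
print.pedigree <- function(x, ...) {
  n <- table(x$individuals$generation)
  cat("<pedigree> ", nrow(x$markers), " markers; ",
      paste(names(n), n, sep = "=", collapse = ", "),
      "; seed ", x$seed, "\n", sep = "")
  bc <- dplyr::filter(x$individuals, .data$generation == "BC")
  print(table(phenotype = bc$phenotype, causal_carrier = bc$causal_carrier))
  invisible(x)
}

#' Backcross individuals of a pedigree
#' @param pedigree a [simulate_cross()] result.
#' @return tibble of BC individuals.
#' @export
bc_individuals <- function(pedigree) {
  dplyr::filter(pedigree$individuals, .data$generation == "BC")
}
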