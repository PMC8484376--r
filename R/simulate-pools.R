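#' Specification of a sequencing pool
#'
#' @param name pool name (becomes the `<name>_ref` / `<name>_alt` columns).
#' @param predicate function taking the BC individual table and returning a
#'   logical membership vector; members contribute two chromosomes each.
#' @param coverage mean reads per variant (Poisson).
#' @param error_rate symmetric per-read allele flip probability in [0, 0.5).
#' @return object of class `pool_spec`.
#' @export
pool_spec <- function(name, predicate, coverage = 45, error_rate = 0.001) {
  stopifnot(is.character(name), length(name) == 1, is.function(predicate),
            coverage > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(name = name, predicate = predicate, coverage = coverage,
                 error_rate = error_rate), class = "pool_spec")
}

#' Default phenotype-based pool pair
#'
#' The carrier-patterned pool (AB or UNCLEAR causal-allele carriers) versus
#' the non-carrier wild-type pool, both at 45x, mirroring how the resequencing
#' pools were assembled from phenotype categories.
#' @param coverage,error_rate passed to [pool_spec()].
#' @return list of two `pool_spec`s named `patterned` and `wildtype`.
#' @export
default_pools <- function(coverage = 45, error_rate = 0.001) {
  list(
    pool_spec("patterned",
              function(df) df$phenotype %in% c("AB", "UNCLEAR") & df$causal_carrier,
              coverage, error_rate),
    pool_spec("wildtype",
              function(df) df$phenotype == "WT" & !df$causal_carrier,
              coverage, error_rate)
  )
}

# One pool's read counts at every marker: depth ~ Poisson(coverage), each read
# drawn from the pool allele frequency and flipped with the error rate.
sample_pool_reads <- function(freq, coverage, error_rate) {
  depth <- rpois(length(freq), coverage)
  p <- freq * (1 - error_rate) + (1 - freq) * error_rate
  alt <- rbinom(length(freq), depth, p)
  list(ref = depth - alt, alt = alt)
}

# Deterministic ref/alt nucleotides per variant (line-B allele is ref).
assign_alleles <- function(n) {
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate pooled resequencing of backcross phenotype pools
#'
#' Every marker of the pedigree is treated as a line-diagnostic biallelic
#' variant (ref = line-B/Leghorn allele, alt = line-A/Fayoumi allele). Pool
#' allele frequencies are the mean alt dosage over members (two chromosomes
#' each); read depths are Poisson around the target coverage and reads are
#' flipped with the pool's error rate.
#'
#' @param pedigree a [simulate_cross()] result.
#' @param pools list of [pool_spec()]s; membership predicates must be disjoint
#'   in intent but this is not enforced.
#' @param seed integer seed.
#' @return tibble `chrom`, `pos`, `ref`, `alt`, then `<pool>_ref`,
#'   `<pool>_alt` per pool.
#' @export
simulate_pool_reads <- function(pedigree, pools = default_pools(), seed = 1) {
  stopifnot(inherits(pedigree, "pedigree"))
  bc <- bc_individuals(pedigree)
  bc_cols <- match(bc$id, colnames(pedigree$hap_m))
  dosage <- pedigree$hap_m[, bc_cols, drop = FALSE] +
    pedigree$hap_p[, bc_cols, drop = FALSE]

  withr::with_seed(seed, {
    alleles <- assign_alleles(nrow(pedigree$markers))
    out <- tibble::tibble(
      chrom = pedigree$markers$chrom, pos = pedigree$markers$pos,
      ref = alleles$ref, alt = alleles$alt
    )
    for (pool in pools) {
      keep <- pool$predicate(bc)
      if (!any(keep)) stop("pool '", pool$name, "' selected no individuals",
                           call. = FALSE)
      freq <- rowMeans(dosage[, keep, drop = FALSE]) / 2
      counts <- sample_pool_reads(freq, pool$coverage, pool$error_rate)
      out[[paste0(pool$name, "_ref")]] <- counts$ref
      out[[paste0(pool$name, "_alt")]] <- counts$alt
    }
    out
  })
}

#' Simulate multi-breed pools with an optional shared IBD segment
#'
#' Each breed has independent allele frequencies drawn from a neutral uniform
#' distribution; a pool of `pool_size` birds is sampled from the breed
#' frequency (binomial over 2 x pool_size chromosomes) and sequenced at low
#' coverage. Inside `ibd_segment` every breed is fixed for one shared
#' haplotype (the reference allele), emulating identity by descent at a shared
#' causal mutation.
#'
#' @param n_breeds number of breed pools (>= 2).
#' @param genome tibble `chrom`, `length_bp`.
#' @param ibd_segment optional `list(chrom =, start =, end =)`.
#' @param pool_size birds per pool.
#' @param coverage mean reads per variant.
#' @param variant_spacing distance between simulated variants (bp).
#' @param error_rate per-read flip probability.
#' @param freq_range support of the neutral breed allele-frequency draw.
#' @param breed_names optional character vector of pool names.
#' @param seed integer seed.
#' @return tibble in the same dialect as [simulate_pool_reads()].
#' @export
simulate_breed_pools <- function(n_breeds = 6,
                                 genome = tibble::tibble(chrom = "chr11",
                                                         length_bp = 19932279),
                                 ibd_segment = NULL,
                                 pool_size = 5, coverage = 10,
                                 variant_spacing = 1000,
                                 error_rate = 0.001,
                                 freq_range = c(0.05, 0.95),
                                 breed_names = paste0("breed", seq_len(n_breeds)),
                                 seed = 1) {
  if (n_breeds < 2) stop("need at least two breed pools", call. = FALSE)
  stopifnot(length(breed_names) == n_breeds, pool_size >= 1)
  if (!is.null(ibd_segment)) {
    i <- match(ibd_segment$chrom, genome$chrom)
    if (is.na(i) || ibd_segment$start < 1 ||
        ibd_segment$end > genome$length_bp[i]) {
      stop("ibd_segment lies outside the genome", call. = FALSE)
    }
  }
  variants <- marker_map(genome, variant_spacing)
  in_ibd <- rep(FALSE, nrow(variants))
  if (!is.null(ibd_segment)) {
    in_ibd <- variants$chrom == ibd_segment$chrom &
      variants$pos >= ibd_segment$start & variants$pos <= ibd_segment$end
  }
  withr::with_seed(seed, {
    alleles <- assign_alleles(nrow(variants))
    out <- tibble::tibble(chrom = variants$chrom, pos = variants$pos,
                          ref = alleles$ref, alt = alleles$alt)
    n_chr <- 2L * pool_size
    for (b in breed_names) {
      p_breed <- runif(nrow(variants), freq_range[1], freq_range[2])
      pool_freq <- rbinom(nrow(variants), n_chr, p_breed) / n_chr
      pool_freq[in_ibd] <- 0   # all pools fixed for the shared haplotype
      counts <- sample_pool_reads(pool_freq, coverage, error_rate)
      out[[paste0(b, "_ref")]] <- counts$ref
      out[[paste0(b, "_alt")]] <- counts$alt
    }
    out
  })
}

#' Pool names present in a counts table
#' @param counts tibble in the `<pool>_ref`/`<pool>_alt` dialect.
#' @return character vector of pool names.
#' @export
pool_names <- function(counts) {
  refs <- grep("_ref$", names(counts), value = TRUE)
  sub("_ref$", "", refs)
}
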