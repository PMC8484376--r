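#' Run configuration for the full mapping pipeline
#'
#' Bundles the simulation configuration and every analysis threshold in one
#' object, so a run is reproducible from `(config, seed)` alone.
#'
#' @param config a [cross_config()].
#' @param model a [phenotype_model()].
#' @param marker_spacing bp between simulated line-diagnostic variants.
#' @param pools list of [pool_spec()]s; the first two are the Fst scan pair.
#' @param window_bp,step_bp,min_variants window-scan parameters.
#' @param alpha Bonferroni family-wise level.
#' @param hp_cutoff fixed Z_Hp cutoff.
#' @param marker_filter_args arguments for [marker_filter()]; `region = NULL`
#'   defaults to the causal chromosome.
#' @param n_breeds,breed_coverage,ibd_segment breed-pool scan settings
#'   (`n_breeds = 0` skips that stage).
#' @param seed integer seed driving every stage.
#' @param out_dir output directory (created).
#' @return object of class `run_config`.
#' @export
run_config <- function(config = cross_config(),
                       model = phenotype_model(),
                       marker_spacing = 10000,
                       pools = default_pools(),
                       window_bp = 30000, step_bp = window_bp,
                       min_variants = 10, alpha = 0.05, hp_cutoff = -4.70,
                       marker_filter_args = list(region = NULL),
                       n_breeds = 0, breed_coverage = 10, ibd_segment = NULL,
                       seed = 1, out_dir = tempfile("poolcross_run_")) {
  if (length(pools) < 2) stop("need at least two pools for the Fst scan",
                              call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

#' Execute the full mapping pipeline
#'
#' Runs simulate -> pool sequencing -> Fst scan -> (optional) breed-pool Hp
#' scan -> marker selection -> genotype matrix + non-recombining interval ->
#' segregation and association statistics, writing each stage's table under
#' the run directory and a JSON manifest (seed, per-stage row counts, file
#' checksums). Re-running with the same configuration and seed reproduces
#' every output byte-identically.
#'
#' @param rc a [run_config()].
#' @return the manifest, invisibly; files under `rc$out_dir`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("poolcross")),
                   seed = rc$seed, stages = list())
  outfile <- function(name) file.path(rc$out_dir, name)
  note <- function(stage, rows, files = character()) {
    manifest$stages[[stage]] <<- list(
      rows = rows,
      files = as.list(tools::md5sum(files))
    )
  }

  ped <- simulate_cross(rc$config, rc$model,
                        marker_map_for(rc$config, rc$marker_spacing),
                        seed = rc$seed)
  note("simulate", nrow(ped$individuals))

  counts <- simulate_pool_reads(ped, rc$pools, seed = rc$seed + 1L)
  write_pool_tsv(counts, outfile("pool_counts.tsv"))
  note("pool_reads", nrow(counts), outfile("pool_counts.tsv"))

  pa <- rc$pools[[1]]$name; pb <- rc$pools[[2]]$name
  fst <- fst_scan(counts, pa, pb, rc$window_bp, rc$step_bp,
                  rc$min_variants, rc$alpha)
  write_pool_tsv(fst, outfile("fst_windows.tsv"))
  note("fst_scan", nrow(fst), outfile("fst_windows.tsv"))

  if (rc$n_breeds >= 2) {
    breeds <- simulate_breed_pools(
      rc$n_breeds, rc$config$chromosomes[, c("chrom", "length_bp")],
      ibd_segment = rc$ibd_segment, coverage = rc$breed_coverage,
      seed = rc$seed + 2L
    )
    hp <- hp_scan(breeds, window_bp = rc$window_bp, step_bp = rc$step_bp,
                  min_variants = rc$min_variants, alpha = rc$alpha,
                  fixed_cutoff = rc$hp_cutoff)
    write_pool_tsv(hp, outfile("hp_windows.tsv"))
    note("hp_scan", nrow(hp), outfile("hp_windows.tsv"))
  }

  mf_args <- rc$marker_filter_args
  if (is.null(mf_args$region)) {
    cl <- rc$config$causal_locus
    len <- rc$config$chromosomes$length_bp[
      match(cl$chrom, rc$config$chromosomes$chrom)]
    mf_args$region <- list(chrom = cl$chrom, start = 1, end = len)
  }
  sel <- select_markers(counts, do.call(marker_filter, mf_args), pa, pb,
                        seed = rc$seed + 3L)
  write_pool_tsv(sel[, c("chrom", "pos", "freq_a", "freq_b")],
                 outfile("selected_markers.tsv"))
  note("select_markers", nrow(sel), outfile("selected_markers.tsv"))

  # genotype the pedigree only at the selected markers plus the causal locus,
  # as a genotyping assay would
  geno_markers <- dplyr::arrange(dplyr::distinct(dplyr::bind_rows(
    sel[, c("chrom", "pos")],
    tibble::tibble(chrom = rc$config$causal_locus$chrom,
                   pos = rc$config$causal_locus$pos)
  )), .data$chrom, .data$pos)
  write_pedigree_tsv(ped, outfile("pedigree.tsv"), markers = geno_markers)
  manifest$stages$simulate$files <- as.list(tools::md5sum(outfile("pedigree.tsv")))

  gm <- build_genotype_matrix(ped, markers = geno_markers)
  interval <- find_nonrecombining_interval(
    gm, carriers = bc_individuals(ped)$causal_carrier
  )
  write_interval_bed(interval, outfile("interval.bed"),
                     outfile("interval_summary.txt"))
  note("interval", interval$last_marker - interval$first_marker + 1L,
       outfile("interval.bed"))

  bc <- bc_individuals(ped)
  seg <- segregation_chisq(c(sum(!bc$causal_carrier), sum(bc$causal_carrier)))
  assoc <- association_table(ped)
  lod <- two_point_lod(bc$causal_carrier, bc$modifier_carrier)
  jsonlite::write_json(
    list(
      segregation = list(observed = seg$observed, chi2 = seg$chi2,
                         df = seg$df, p = seg$p),
      lod = list(n = lod$n, r = lod$r, r_hat = lod$r_hat, lod = lod$lod),
      association = lapply(assoc, function(t) as.data.frame.matrix(t))
    ),
    outfile("linkage_report.json"), auto_unbox = TRUE, digits = NA
  )
  note("linkage", seg$df + 1L, outfile("linkage_report.json"))

  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
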