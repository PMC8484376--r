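#' Write pool counts as TSV
#'
#' Flat dialect: `chrom`, `pos`, `ref`, `alt`, then `<pool>_ref`,
#' `<pool>_alt` per pool.
#'
#' @param counts counts tibble.
#' @param path output file.
#' @export
write_pool_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read pool counts from TSV
#' @param path file in the [write_pool_tsv()] dialect.
#' @return counts tibble.
#' @export
read_pool_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write pool counts as VCF with per-pool AD fields
#'
#' Minimal VCF 4.2 with one sample column per pool and `GT:AD` per genotype
#' field; genotypes are left as `./.` (pools have no single genotype) and AD
#' carries `ref,alt` read depths.
#'
#' @inheritParams write_pool_tsv
#' @export
write_pool_vcf <- function(counts, path) {
  pools <- pool_names(counts)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolcross",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t")
  )
  geno <- sapply(pools, function(p) {
    paste0("./.:", counts[[paste0(p, "_ref")]], ",", counts[[paste0(p, "_alt")]])
  })
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  body <- paste(counts$chrom, counts$pos, ".", counts$ref, counts$alt, ".",
                "PASS", ".", "GT:AD",
                apply(geno, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read pool counts from a VCF with per-sample AD
#'
#' Parses biallelic records of a VCF whose samples are pools with `AD`
#' (ref,alt depth) in the genotype field; multi-allelic records are skipped
#' with a message. Requires the `vcfR` package.
#'
#' @param path VCF file.
#' @return counts tibble in the [write_pool_tsv()] dialect.
#' @export
read_pool_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_pool_vcf requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT)
  if (any(!biallelic)) {
    message(sum(!biallelic), " multi-allelic record(s) skipped")
  }
  ad <- vcfR::extract.gt(v, element = "AD")[biallelic, , drop = FALSE]
  out <- tibble::tibble(
    chrom = fix$CHROM[biallelic], pos = as.integer(fix$POS[biallelic]),
    ref = fix$REF[biallelic], alt = fix$ALT[biallelic]
  )
  for (p in colnames(ad)) {
    parts <- do.call(rbind, strsplit(ad[, p], ",", fixed = TRUE))
    out[[paste0(p, "_ref")]] <- as.integer(parts[, 1])
    out[[paste0(p, "_alt")]] <- as.integer(parts[, 2])
  }
  out
}

#' Read pool counts from VCF or TSV by extension
#' @param path `.vcf` or `.tsv`/`.txt` file.
#' @return counts tibble.
#' @export
read_pool_counts <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) read_pool_vcf(path)
  else read_pool_tsv(path)
}

#' Write a pedigree as TSV
#'
#' One row per individual — `id`, `sire`, `dam`, `sex`, `generation`,
#' `phenotype` — followed by one column per marker with the genotype code
#' (line-A allele dosage 0/1/2).
#'
#' @param pedigree a [simulate_cross()] result.
#' @param path output file.
#' @param markers optional marker subset (`chrom`, `pos`).
#' @export
write_pedigree_tsv <- function(pedigree, path, markers = NULL) {
  rows <- seq_len(nrow(pedigree$markers))
  mtab <- pedigree$markers
  if (!is.null(markers)) {
    rows <- match(paste(markers$chrom, markers$pos),
                  paste(mtab$chrom, mtab$pos))
    rows <- rows[!is.na(rows)]
    mtab <- mtab[rows, ]
  }
  dosage <- t(pedigree$hap_m[rows, , drop = FALSE] +
                pedigree$hap_p[rows, , drop = FALSE])
  colnames(dosage) <- paste0(mtab$chrom, "_", mtab$pos)
  df <- cbind(
    as.data.frame(pedigree$individuals[, c("id", "sire", "dam", "sex",
                                           "generation", "phenotype")]),
    as.data.frame(dosage)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an interval report as BED plus a text summary
#'
#' @param interval a [find_nonrecombining_interval()] result.
#' @param bed_path BED output (0-based half-open).
#' @param summary_path optional human-readable summary.
#' @export
write_interval_bed <- function(interval, bed_path, summary_path = NULL) {
  bed <- data.frame(chrom = interval$chrom, start = interval$start - 1,
                    end = interval$end, name = "non_recombining_interval")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(summary_path)) {
    writeLines(c(
      sprintf("Non-recombining interval: %s:%d-%d (markers %d-%d)",
              interval$chrom, interval$start, interval$end,
              interval$first_marker, interval$last_marker),
      sprintf("Informative meioses: %d", interval$n_informative_meioses),
      sprintf("Flanking recombinant markers: %s / %s",
              format(interval$border_start), format(interval$border_end)),
      sprintf("Recombinants at borders: %s",
              paste(interval$n_recombinants_at_borders, collapse = " / "))
    ), summary_path)
  }
  invisible(bed_path)
}
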