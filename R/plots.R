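#' Manhattan-style plot of a window scan
#'
#' Window Z scores along the genome, faceted by chromosome, with the
#' significance threshold drawn (Bonferroni z for the scan's tail, and the
#' fixed cutoff when present).
#'
#' @param windows output of [fst_scan()] or [hp_scan()].
#' @param cutoff optional horizontal reference line (e.g. -4.70).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(windows, cutoff = NULL) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.6) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "position (Mb)", y = "window Z score") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' Heatmap of a backcross genotype matrix
#'
#' Individuals (rows, grouped by phenotype) by markers (columns), coloured by
#' genotype code: homozygous wild-type, heterozygous, homozygous founder-line.
#'
#' @param gm a [build_genotype_matrix()] result.
#' @return a ggplot object.
#' @export
plot_genotype_matrix <- function(gm) {
  df <- tidyr::pivot_longer(
    cbind(tibble::tibble(marker = seq_len(nrow(gm$codes))),
          as.data.frame(gm$codes)),
    -"marker", names_to = "id", values_to = "code"
  )
  pheno <- gm$individuals$phenotype[match(df$id, gm$individuals$id)]
  df$id <- factor(df$id, levels = gm$individuals$id[order(gm$individuals$phenotype)])
  df$phenotype <- pheno
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$id,
                                   fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(HOM_WT = "gold", HET = "orange",
                                          HOM_FAY = "red3", MISSING = "grey80")) +
    ggplot2::labs(x = "marker index", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Heatmap of pool states around an anchor gene
#'
#' @param states output of [pool_state_matrix()].
#' @return a ggplot object.
#' @export
plot_pool_states <- function(states) {
  df <- tidyr::pivot_longer(states, -c("chrom", "pos"),
                            names_to = "pool", values_to = "state")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$pool,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(FIXED_REF = "gold",
                                          FIXED_ALT = "red3",
                                          SEGREGATING = "orange",
                                          MISSING = "grey80")) +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
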