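# ggplot2 figures for window statistics, region calls and expression.

#' Coverage and SNP-density tracks for a window table
#'
#' @param object a combined window table (from [combine_sexes()] or
#'   [classify_windows()]).
#' @param ... unused.
#' @return A ggplot with normalized coverage and SNP density per sex along
#'   the chromosome.
#' @export
autoplot.ztr_windows <- function(object, ...) {
  w <- tibble::as_tibble(object)
  w <- w[!w$excluded, ]
  long <- dplyr::bind_rows(
    tibble::tibble(chrom = w$chrom, mb = w$start / 1e6, sex = "female",
                   track = "normalized coverage", value = w$norm_cov_f),
    tibble::tibble(chrom = w$chrom, mb = w$start / 1e6, sex = "male",
                   track = "normalized coverage", value = w$norm_cov_m),
    tibble::tibble(chrom = w$chrom, mb = w$start / 1e6, sex = "female",
                   track = "SNP density / window", value = w$snp_density_f),
    tibble::tibble(chrom = w$chrom, mb = w$start / 1e6, sex = "male",
                   track = "SNP density / window", value = w$snp_density_m)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mb, y = .data$value,
                                     colour = .data$sex)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(track ~ chrom, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Region-call track
#'
#' @param object a `ztr_regions` tibble from [merge_calls()].
#' @param ... unused.
#' @export
autoplot.ztr_regions <- function(object, ...) {
  r <- tidy(object)
  r <- r[!r$label %in% c("EXCLUDED"), ]
  ggplot2::ggplot(r) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = 0, ymax = 1, fill = .data$label
    )) +
    ggplot2::facet_grid(.data$chrom ~ .) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "call") +
    ggplot2::theme_minimal()
}

#' Expression heatmap (log1p TPM)
#'
#' @param object a `ztr_expression` from [expression_profile()].
#' @param ... unused.
#' @export
autoplot.ztr_expression <- function(object, ...) {
  p <- object$profile
  p$condition <- paste(p$species, p$tissue, p$sex, sep = ".")
  ggplot2::ggplot(p, ggplot2::aes(x = .data$condition, y = .data$gene,
                                  fill = .data$log1p_tpm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + TPM)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
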