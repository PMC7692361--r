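# GATK-style hard filtering of variant records, the heterozygous
# allele-fraction window, and per-window SNP density.

HARD_FILTER_RULES <- tibble::tibble(
  annotation = c("FS", "QD", "MQ", "SOR", "MQRankSum", "ReadPosRankSum"),
  direction = c("gt", "lt", "lt", "gt", "lt", "lt"),
  threshold = c(10.0, 2.0, 50.0, 1.5, -1.5, -8.0)
)

#' Apply hard filters to variant records
#'
#' Fails a record when any annotation violates its threshold: FS > 10,
#' QD < 2, MQ < 50, SOR > 1.5, MQRankSum < -1.5, ReadPosRankSum < -8.
#' Additionally any SNP belonging to a cluster of two or more SNPs within a
#' 10-bp span fails with reason `"cluster"` (indels are exempt from the
#' cluster rule). All applicable fail reasons are recorded; a missing
#' (`NA`) annotation means that criterion is not applied.
#'
#' @param records variant tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vtype` (`"SNP"`/`"INDEL"`), the six annotation columns, and
#'   `allele_fraction`; must be sorted by (chrom, pos).
#' @param cluster_window span in bp within which two SNPs form a cluster;
#'   default 10.
#' @param cluster_size minimum SNPs per cluster; default 2.
#' @return `records` with columns `filter` (`"PASS"` or semicolon-joined
#'   reasons) and `pass` (logical).
#' @export
hard_filter <- function(records, cluster_window = 10L, cluster_size = 2L) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (n == 0L) {
    records$filter <- character(0)
    records$pass <- logical(0)
    return(records)
  }
  ord <- order(records$chrom, records$pos)
  if (!identical(ord, seq_len(n))) rlang::abort("variant records must be sorted by (chrom, pos)")

  reasons <- vector("list", n)
  for (i in seq_len(nrow(HARD_FILTER_RULES))) {
    ann <- HARD_FILTER_RULES$annotation[i]
    if (!ann %in% names(records)) next
    val <- records[[ann]]
    bad <- if (HARD_FILTER_RULES$direction[i] == "gt") {
      val > HARD_FILTER_RULES$threshold[i]
    } else {
      val < HARD_FILTER_RULES$threshold[i]
    }
    bad[is.na(bad)] <- FALSE
    for (j in which(bad)) reasons[[j]] <- c(reasons[[j]], ann)
  }

  # SNP cluster rule: two SNPs whose positions fit inside one
  # `cluster_window`-bp span (|p - q| < cluster_window) form a cluster.
  is_snp <- records$vtype == "SNP"
  for (ch in unique(records$chrom)) {
    idx <- which(is_snp & records$chrom == ch)
    if (length(idx) < cluster_size) next
    pos <- records$pos[idx]
    gap_prev <- c(Inf, diff(pos))
    gap_next <- c(diff(pos), Inf)
    clustered <- pmin(gap_prev, gap_next) < cluster_window
    for (j in idx[clustered]) reasons[[j]] <- c(reasons[[j]], "cluster")
  }

  records$filter <- vapply(reasons, function(r) {
    if (is.null(r)) "PASS" else paste(r, collapse = ";")
  }, character(1))
  records$pass <- records$filter == "PASS"
  records
}

#' Retain heterozygous-looking variants by allele fraction
#'
#' For a single diploid individual a true heterozygote has expected
#' alternate-allele fraction 0.5; records outside the closed interval
#' `[af_min, af_max]` are dropped. Only records that passed [hard_filter()]
#' are considered. Records with a missing allele fraction are dropped and
#' counted in the `n_missing_af` attribute with a warning.
#'
#' @param records hard-filtered variant tibble (with `pass`).
#' @param af_min,af_max inclusive allele-fraction bounds; defaults 0.3, 0.7.
#' @return The retained records; attributes `n_missing_af`,
#'   `n_af_dropped`.
#' @export
allele_fraction_filter <- function(records, af_min = 0.3, af_max = 0.7) {
  records <- tibble::as_tibble(records)
  if (!"pass" %in% names(records)) rlang::abort("run hard_filter() first")
  passed <- records[records$pass, , drop = FALSE]
  missing_af <- is.na(passed$allele_fraction)
  if (any(missing_af)) {
    rlang::warn(sprintf("%d records with missing allele fraction dropped", sum(missing_af)))
  }
  ok <- !missing_af & passed$allele_fraction >= af_min & passed$allele_fraction <= af_max
  out <- passed[ok, , drop = FALSE]
  attr(out, "n_missing_af") <- sum(missing_af)
  attr(out, "n_af_dropped") <- sum(!ok & !missing_af)
  out
}

#' Per-window SNP density for one sex
#'
#' Counts retained SNPs per coverage window: a SNP at 1-based position `pos`
#' belongs to the window whose 0-based half-open interval contains
#' `pos - 1`. Density is defined as the count per window. Indels are never
#' counted.
#'
#' @param records retained variant records (after [hard_filter()] and
#'   [allele_fraction_filter()]).
#' @param windows window table from [window_coverage()].
#' @param sex `"female"` or `"male"`; controls the output column suffix.
#' @return `windows` with added columns `snp_count_<f|m>` and
#'   `snp_density_<f|m>`.
#' @export
snp_density <- function(records, windows, sex) {
  stopifnot_scalar_sex(sex)
  suffix <- if (sex == "female") "f" else "m"
  windows <- tibble::as_tibble(windows)
  records <- tibble::as_tibble(records)
  snps <- records[records$vtype == "SNP", , drop = FALSE]
  counts <- integer(nrow(windows))
  if (nrow(snps) > 0L) {
    for (ch in unique(windows$chrom)) {
      wi <- which(windows$chrom == ch)
      p0 <- snps$pos[snps$chrom == ch] - 1L
      if (length(p0) == 0L) next
      # windows are a uniform tiling from 0; bin by integer division
      wsize <- windows$end[wi[1]] - windows$start[wi[1]]
      bin <- p0 %/% wsize
      tab <- table(bin[bin < length(wi)])
      counts[wi[as.integer(names(tab)) + 1L]] <- as.integer(tab)
    }
  }
  windows[[paste0("snp_count_", suffix)]] <- counts
  windows[[paste0("snp_density_", suffix)]] <- as.numeric(counts)
  class(windows) <- unique(c("ztr_windows", class(windows)))
  windows
}
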