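# Haploinsufficiency percentiles and expression profiling of surviving ZTR
# genes. (Branch dN/dS lives in ng86.R.)

#' Haploinsufficiency percentile ranks
#'
#' Ranks query genes within the distribution of haploinsufficiency scores
#' of a background gene set (typically all Z-linked genes). The percentile
#' of a query is `100 * #(background scores <= query score) / #background`.
#' A high percentile marks a dosage-sensitive gene: one copy is predicted
#' to be insufficient for normal function.
#'
#' @param hi_table data frame with columns `gene` and `score` in `[0, 1]`.
#' @param background_genes character vector of background gene names
#'   (must be present in `hi_table`).
#' @param query_genes character vector of query gene names; queries absent
#'   from the table are reported with `NA` percentile.
#' @return A list: `percentiles` tibble (`gene`, `score`, `percentile`,
#'   `in_table`), and `ecdf` tibble (`score`, `cumulative_fraction`) over
#'   the background for plotting.
#' @export
hi_percentile <- function(hi_table, background_genes, query_genes) {
  hi_table <- tibble::as_tibble(hi_table)
  if (!all(c("gene", "score") %in% names(hi_table))) {
    rlang::abort("hi_table needs columns `gene` and `score`")
  }
  if (any(hi_table$score < 0 | hi_table$score > 1, na.rm = TRUE)) {
    rlang::abort("haploinsufficiency scores must lie in [0, 1]")
  }
  bg <- hi_table$score[match(background_genes, hi_table$gene)]
  bg <- bg[!is.na(bg)]
  if (length(bg) == 0L) rlang::abort("empty background")
  q_scores <- hi_table$score[match(query_genes, hi_table$gene)]
  missing <- is.na(q_scores)
  if (any(missing)) {
    rlang::warn(paste0("query genes missing from table: ",
                       paste(query_genes[missing], collapse = ", ")))
  }
  percentiles <- tibble::tibble(
    gene = query_genes,
    score = q_scores,
    percentile = ifelse(missing, NA_real_,
                        100 * vapply(q_scores, function(s) mean(bg <= s), numeric(1))),
    in_table = !missing
  )
  sorted <- sort(bg)
  ecdf_tbl <- tibble::tibble(
    score = sorted,
    cumulative_fraction = seq_along(sorted) / length(sorted)
  )
  list(percentiles = percentiles, ecdf = ecdf_tbl)
}

#' Replicate-averaged expression profile with gonad-bias flagging
#'
#' For each (gene, species, tissue, sex) the mean TPM over replicates is
#' taken and reported as `log1p_tpm = log(1 + mean TPM)` (natural log). A
#' gene is flagged gonad-biased in a species when its female-gonad mean TPM
#' is at least `bias_fold_threshold` times the maximum mean over all other
#' (tissue, sex) conditions of that species. Conditions absent for a
#' species are left out of the matrix (blank cells) and excluded from the
#' bias comparison.
#'
#' @param expression long-format data frame: `species`, `tissue`, `sex`,
#'   `replicate`, `gene`, `tpm` (all TPM >= 0).
#' @param bias_fold_threshold fold difference defining bias; default 2.
#' @param gonad_tissue name of the gonad tissue; default `"gonad"`.
#' @return A `ztr_expression` list: `profile` tibble (per gene x species x
#'   tissue x sex: `mean_tpm`, `log1p_tpm`, `n_replicates`), and `bias`
#'   tibble (per gene x species: `female_gonad_tpm`, `max_other_tpm`,
#'   `gonad_biased`).
#' @export
expression_profile <- function(expression, bias_fold_threshold = 2,
                               gonad_tissue = "gonad") {
  expression <- tibble::as_tibble(expression)
  needed <- c("species", "tissue", "sex", "replicate", "gene", "tpm")
  if (!all(needed %in% names(expression))) {
    rlang::abort(paste0("expression table needs columns: ",
                        paste(needed, collapse = ", ")))
  }
  if (any(expression$tpm < 0, na.rm = TRUE)) rlang::abort("negative TPM")
  profile <- expression |>
    dplyr::group_by(.data$gene, .data$species, .data$tissue, .data$sex) |>
    dplyr::summarise(
      mean_tpm = mean(.data$tpm),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(log1p_tpm = log1p(.data$mean_tpm))

  has_fg <- any(profile$tissue == gonad_tissue & profile$sex == "female")
  if (!has_fg) {
    rlang::warn("no female gonad condition present; bias flags unavailable")
  }
  bias <- profile |>
    dplyr::group_by(.data$gene, .data$species) |>
    dplyr::summarise(
      female_gonad_tpm = {
        fg <- .data$mean_tpm[.data$tissue == gonad_tissue & .data$sex == "female"]
        if (length(fg)) fg[1] else NA_real_
      },
      max_other_tpm = {
        other <- .data$mean_tpm[!(.data$tissue == gonad_tissue & .data$sex == "female")]
        if (length(other)) max(other) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      gonad_biased = !is.na(.data$female_gonad_tpm) & !is.na(.data$max_other_tpm) &
        .data$female_gonad_tpm >= bias_fold_threshold * .data$max_other_tpm
    )
  structure(
    list(profile = profile, bias = bias,
         bias_fold_threshold = bias_fold_threshold,
         gonad_tissue = gonad_tissue),
    class = "ztr_expression"
  )
}

#' @export
tidy.ztr_expression <- function(x, ...) x$profile

#' @export
glance.ztr_expression <- function(x, ...) {
  tibble::tibble(
    n_genes = length(unique(x$profile$gene)),
    n_species = length(unique(x$profile$species)),
    n_biased = sum(x$bias$gonad_biased, na.rm = TRUE),
    bias_fold_threshold = x$bias_fold_threshold
  )
}
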