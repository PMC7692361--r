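# Per-gene fate on the W copy: deleted, partially deleted, pseudogene
# (frameshift / premature stop), or intact.

#' Build a gene model table
#'
#' @param name gene names.
#' @param start,end 0-based half-open gene intervals on Z.
#' @param strand `"+"` or `"-"`.
#' @param cds list of CDS segment tables (`start`, `end`, 0-based
#'   half-open, phase 0, in genomic order); defaults to single-exon CDS
#'   spanning the gene.
#' @return Tibble with a `cds` list column.
#' @export
gene_models <- function(name, start, end, strand = "+", cds = NULL) {
  n <- length(name)
  strand <- rep_len(strand, n)
  if (is.null(cds)) {
    cds <- purrr::map2(start, end, function(s, e) tibble::tibble(start = s, end = e))
  }
  tibble::tibble(name = name, start = start, end = end, strand = strand, cds = cds)
}

#' Intersect genes with called W-deletions
#'
#' A gene wholly inside a W-deletion is `deleted`; a gene overlapping a
#' deletion boundary is `partial_deletion` (even if the residual ORF could
#' be intact); other genes are left `pending` for ORF assessment.
#'
#' @param genes gene model tibble (see [gene_models()]).
#' @param w_deletions a [call_w_deletions()] result (or tibble with
#'   `start`, `end`).
#' @param envelope optional ZTR envelope `c(start, end)`; genes outside it
#'   are skipped with a warning.
#' @return Tibble `name`, `fate` (`deleted` / `partial_deletion` /
#'   `pending`), `detail`.
#' @export
intersect_gene_deletions <- function(genes, w_deletions, envelope = NULL) {
  genes <- tibble::as_tibble(genes)
  envelope <- envelope %||% attr(w_deletions, "envelope")
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!is.null(envelope) && (g$start < envelope[1] || g$end > envelope[2])) {
      rlang::warn(sprintf("gene %s outside the ZTR envelope; skipped", g$name))
      return(NULL)
    }
    fate <- "pending"
    detail <- ""
    for (j in seq_len(nrow(w_deletions))) {
      ds <- w_deletions$start[j]
      de <- w_deletions$end[j]
      if (g$start >= ds && g$end <= de) {
        fate <- "deleted"
        detail <- sprintf("inside W-deletion [%d, %d)", ds, de)
        break
      }
      if (g$start < de && g$end > ds) {
        fate <- "partial_deletion"
        detail <- sprintf("overlaps W-deletion [%d, %d)", ds, de)
        break
      }
    }
    tibble::tibble(name = g$name, fate = fate, detail = detail)
  })
  bind_or_template(purrr::compact(rows),
                   tibble::tibble(name = character(), fate = character(),
                                  detail = character()))
}

#' Assess the open reading frame of a gene on the W pseudo-sequence
#'
#' Lifts the gene's CDS segments onto the W pseudo-sequence, concatenates
#' them (reverse-complemented for minus-strand genes), and translates with
#' the standard genetic code. The gene is a `pseudogene` with cause
#' `frameshift` when the net indel length inside the CDS is not a multiple
#' of 3, `premature_stop` when an in-frame stop precedes the annotated
#' terminal codon, or `both`. A CDS segment that cannot be lifted (inside a
#' W-deletion) yields `partial_deletion`. Otherwise the gene is `intact`.
#'
#' @param gene one row of a gene model tibble.
#' @param z_reference the Z reference sequence (string or DNAStringSet).
#' @param wpseq a `ztr_wpseq` from [build_w_pseudosequence()].
#' @param deletions optional [call_w_deletions()] result.
#' @return One-row tibble `name`, `fate`, `pseudogene_cause`, `detail`.
#' @export
assess_orf <- function(gene, z_reference, wpseq, deletions = NULL) {
  gene <- tibble::as_tibble(gene)
  stopifnot(nrow(gene) == 1L)
  ref_seq <- as_reference_string(z_reference)
  cds <- gene$cds[[1]]
  cds <- cds[order(cds$start), , drop = FALSE]

  z_cds <- paste(substring(ref_seq, cds$start + 1L, cds$end), collapse = "")
  z_len <- nchar(z_cds)
  w_parts <- character(nrow(cds))
  for (j in seq_len(nrow(cds))) {
    lift <- liftover(wpseq, c(cds$start[j], cds$end[j]), deletions = deletions)
    if (lift$status != "mapped") {
      return(tibble::tibble(
        name = gene$name, fate = "partial_deletion", pseudogene_cause = NA_character_,
        detail = sprintf("CDS segment %d not liftable (%s)", j, lift$status)
      ))
    }
    w_parts[j] <- substr(wpseq$sequence, lift$w_start + 1L, lift$w_end)
  }
  w_cds <- paste(w_parts, collapse = "")
  if (gene$strand == "-") {
    w_cds <- revcomp(w_cds)
    z_cds <- revcomp(z_cds)
  }

  # input sanity: the Z model should encode a clean ORF
  z_aa <- translate_codons(split_codons(z_cds))
  if (any(z_aa[-length(z_aa)] == "*")) {
    rlang::warn(sprintf("gene %s: Z CDS contains an internal stop codon", gene$name))
  }

  frameshift <- (nchar(w_cds) - z_len) %% 3L != 0L
  n_complete <- nchar(w_cds) %/% 3L
  premature <- FALSE
  if (n_complete >= 2L) {
    w_codons <- substring(w_cds, seq(1L, by = 3L, length.out = n_complete),
                          seq(3L, by = 3L, length.out = n_complete))
    w_aa <- translate_codons(w_codons)
    premature <- any(w_aa[seq_len(n_complete - 1L)] == "*")
  }
  cause <- if (frameshift && premature) "both"
    else if (frameshift) "frameshift"
    else if (premature) "premature_stop"
    else NA_character_
  tibble::tibble(
    name = gene$name,
    fate = if (is.na(cause)) "intact" else "pseudogene",
    pseudogene_cause = cause,
    detail = sprintf("W CDS %d bp vs Z CDS %d bp", nchar(w_cds), z_len)
  )
}

#' Classify the fate of every gene in a ZTR
#'
#' Combines [intersect_gene_deletions()] with [assess_orf()]: genes hit by
#' a W-deletion are deleted or partially deleted, the remainder are
#' assessed for frameshifts and premature stops on the W pseudo-sequence.
#'
#' @inheritParams assess_orf
#' @param genes gene model tibble.
#' @return Tibble `name`, `fate`, `pseudogene_cause`, `detail`.
#' @export
gene_fates <- function(genes, z_reference, wpseq, deletions) {
  genes <- tibble::as_tibble(genes)
  provisional <- intersect_gene_deletions(genes, deletions,
                                          envelope = wpseq$source_interval)
  rows <- lapply(seq_len(nrow(provisional)), function(i) {
    if (provisional$fate[i] != "pending") {
      return(tibble::tibble(
        name = provisional$name[i], fate = provisional$fate[i],
        pseudogene_cause = NA_character_, detail = provisional$detail[i]
      ))
    }
    assess_orf(genes[genes$name == provisional$name[i], ],
               z_reference, wpseq, deletions = deletions)
  })
  bind_or_template(rows, tibble::tibble(
    name = character(), fate = character(),
    pseudogene_cause = character(), detail = character()
  ))
}

#' Summarize gene fates across lineages
#'
#' @param fates a fate tibble (from [gene_fates()]) with an optional
#'   `lineage` column, or a named list of fate tibbles (names become
#'   lineages).
#' @return Tibble with one row per lineage plus a pooled row: counts per
#'   fate, `n_functional` (intact genes), `survival_fraction`, and
#'   `percent_lost` (non-intact genes, rounded to the nearest integer).
#' @export
summarize_fates <- function(fates) {
  if (is.data.frame(fates)) {
    if (!"lineage" %in% names(fates)) fates$lineage <- "all"
  } else {
    fates <- dplyr::bind_rows(purrr::imap(fates, function(f, nm) {
      f <- tibble::as_tibble(f)
      f$lineage <- nm
      f
    }))
  }
  if (nrow(fates) == 0L) rlang::abort("at least one gene fate is required")
  one <- function(f, lineage) {
    n <- nrow(f)
    intact <- sum(f$fate == "intact")
    tibble::tibble(
      lineage = lineage, n_genes = n,
      intact = intact,
      partial_deletion = sum(f$fate == "partial_deletion"),
      deleted = sum(f$fate == "deleted"),
      pseudogene = sum(f$fate == "pseudogene"),
      n_functional = intact,
      survival_fraction = intact / n,
      percent_lost = round(100 * (n - intact) / n)
    )
  }
  per <- dplyr::bind_rows(lapply(split(fates, fates$lineage), function(f) {
    one(f, f$lineage[1])
  }))
  pooled <- one(fates, "pooled")
  if (nrow(per) == 1L && per$lineage[1] == "all") {
    out <- dplyr::bind_rows(per)
  } else {
    out <- dplyr::bind_rows(per, pooled)
  }
  out
}
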