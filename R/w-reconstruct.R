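# W-linked pseudo-sequence construction from female variants, Z->W
# coordinate mapping, and window-resolution W-deletion calls.

#' Build the W-linked pseudo-sequence for a ZTR
#'
#' Substitutes the alternate alleles of retained female heterozygous
#' variants into the Z reference over the ZTR interval. Because a young ZTR
#' has not yet diverged far from its parental Z copy, female heterozygous
#' sites inside it are read as Z-W divergence and the alternate allele is
#' assigned to the W haplotype (alternate-reference logic; no phasing is
#' attempted). Variants are applied left to right; any variant whose
#' reference span intersects an already-applied span is skipped and
#' reported.
#'
#' @param reference the Z chromosome sequence: a character string, a named
#'   character vector, or a `Biostrings::DNAStringSet` (first sequence
#'   used).
#' @param ztr_interval numeric length-2, 0-based half-open `c(start, end)`
#'   on the reference.
#' @param variants tibble of retained variants (`pos` 1-based, `ref`,
#'   `alt`), sorted by position, all inside the interval.
#' @return A `ztr_wpseq` object: `sequence`, `applied_variants`,
#'   `skipped_variants`, `coord_map` (tibble `z_pos`, `w_pos`,
#'   `cumulative_offset` at each indel breakpoint), `source_interval`,
#'   `chrom`.
#' @export
build_w_pseudosequence <- function(reference, ztr_interval, variants) {
  ref_seq <- as_reference_string(reference)
  start0 <- as.integer(ztr_interval[1])
  end0 <- as.integer(ztr_interval[2])
  if (start0 < 0L || end0 > nchar(ref_seq) || start0 >= end0) {
    rlang::abort("ztr_interval out of reference bounds")
  }
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) > 0L) {
    if (is.unsorted(variants$pos)) rlang::abort("variants must be sorted by position")
    inside <- variants$pos > start0 &
      (variants$pos + nchar(variants$ref) - 1L) <= end0
    if (!all(inside)) rlang::abort("variants outside the ZTR interval")
  }

  applied <- logical(nrow(variants))
  last_end <- start0 # 0-based end of last consumed reference span
  pieces <- character(0)
  offset <- 0L
  map_z <- integer(0)
  map_off <- integer(0)
  for (i in seq_len(nrow(variants))) {
    pos0 <- variants$pos[i] - 1L
    ref_allele <- variants$ref[i]
    alt_allele <- variants$alt[i]
    if (pos0 < last_end) next # overlaps an applied span: skip
    obs <- substr(ref_seq, pos0 + 1L, pos0 + nchar(ref_allele))
    if (obs != ref_allele) {
      rlang::abort(sprintf(
        "reference allele mismatch at position %d: expected %s, reference has %s",
        variants$pos[i], ref_allele, obs
      ))
    }
    pieces <- c(pieces, substr(ref_seq, last_end + 1L, pos0), alt_allele)
    last_end <- pos0 + nchar(ref_allele)
    applied[i] <- TRUE
    delta <- nchar(alt_allele) - nchar(ref_allele)
    if (delta != 0L) {
      offset <- offset + delta
      map_z <- c(map_z, last_end) # 0-based end of ref span
      map_off <- c(map_off, offset)
    }
  }
  pieces <- c(pieces, substr(ref_seq, last_end + 1L, end0))
  w_seq <- paste(pieces, collapse = "")

  coord_map <- tibble::tibble(
    z_pos = map_z,
    cumulative_offset = map_off,
    w_pos = map_z - start0 + map_off
  )
  structure(
    list(
      sequence = w_seq,
      applied_variants = variants[applied, , drop = FALSE],
      skipped_variants = variants[!applied & seq_len(nrow(variants)) > 0, , drop = FALSE],
      coord_map = coord_map,
      source_interval = c(start0, end0),
      chrom = if ("chrom" %in% names(variants) && nrow(variants) > 0L) variants$chrom[1] else NA_character_
    ),
    class = "ztr_wpseq"
  )
}

as_reference_string <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    return(as.character(reference[[1]]))
  }
  if (is.character(reference)) {
    return(unname(reference[1]))
  }
  rlang::abort("reference must be a character string or DNAStringSet")
}

#' @export
print.ztr_wpseq <- function(x, ...) {
  cat(sprintf(
    "<ztr_wpseq> %d bp W pseudo-sequence from Z interval [%d, %d) (%d variants applied, %d skipped)\n",
    nchar(x$sequence), x$source_interval[1], x$source_interval[2],
    nrow(x$applied_variants), nrow(x$skipped_variants)
  ))
  invisible(x)
}

#' Call W-deletions inside a ZTR envelope
#'
#' Interior runs of hemizygous-looking windows inside a ZTR call (female
#' coverage back at one copy) are read as sequence lost from the W copy.
#' Each candidate run spanning at least `min_run` windows becomes a
#' W-deletion; the retained W length is the envelope length minus the total
#' deleted length.
#'
#' @param ztr_call a single-row `ZTR` region call from [merge_calls()], or
#'   `NULL` when `envelope`/`candidates` are given directly.
#' @param envelope 0-based half-open `c(start, end)` of the ZTR on Z.
#' @param candidates list of 0-based half-open candidate intervals.
#' @param min_run minimum deletion size in windows; default 2.
#' @param window_size window width in bp; default 50,000.
#' @return A `ztr_wdeletions` object: tibble of `start`, `end`,
#'   `length` with attributes `envelope`, `envelope_length`,
#'   `total_deleted`, `retained_length`.
#' @export
call_w_deletions <- function(ztr_call = NULL, envelope = NULL, candidates = NULL,
                             min_run = 2L, window_size = 50000L) {
  if (!is.null(ztr_call)) {
    ztr_call <- tibble::as_tibble(ztr_call)
    if (nrow(ztr_call) != 1L || ztr_call$label != "ZTR") {
      rlang::abort("ztr_call must be a single ZTR region call")
    }
    envelope <- c(ztr_call$start, ztr_call$end)
    candidates <- ztr_call$w_deletion_candidates[[1]]
  }
  if (is.null(envelope)) rlang::abort("an envelope interval is required")
  candidates <- candidates %||% list()
  keep <- vapply(candidates, function(iv) {
    (iv[2] - iv[1]) / window_size >= min_run
  }, logical(1))
  dels <- candidates[keep]
  dels <- dels[order(vapply(dels, `[`, numeric(1), 1))]
  out <- tibble::tibble(
    start = vapply(dels, `[`, numeric(1), 1),
    end = vapply(dels, `[`, numeric(1), 2)
  )
  out$length <- out$end - out$start
  env_len <- envelope[2] - envelope[1]
  total_del <- sum(out$length)
  structure(
    out,
    class = c("ztr_wdeletions", class(out)),
    envelope = envelope,
    envelope_length = env_len,
    total_deleted = total_del,
    retained_length = env_len - total_del
  )
}

#' @export
glance.ztr_wdeletions <- function(x, ...) {
  tibble::tibble(
    envelope_length = attr(x, "envelope_length"),
    n_deletions = nrow(x),
    total_deleted = attr(x, "total_deleted"),
    retained_length = attr(x, "retained_length"),
    retained_mb = round(attr(x, "retained_length") / 1e6, 1)
  )
}

#' Lift a Z interval onto the W pseudo-sequence
#'
#' Maps a 0-based half-open Z interval through the indel offsets of a
#' reconstructed W pseudo-sequence. Intervals wholly inside a called
#' W-deletion return status `"deleted"`; partial overlap returns the mapped
#' retained part flagged `"partial"`.
#'
#' @param wpseq a `ztr_wpseq` object (or its `coord_map` tibble plus
#'   `source_interval` attribute-compatible list).
#' @param z_interval 0-based half-open `c(start, end)` on Z, inside the
#'   envelope.
#' @param deletions optional `ztr_wdeletions` (or tibble with `start`,
#'   `end`) of called W-deletions.
#' @return One-row tibble: `status` (`"mapped"`, `"partial"`,
#'   `"deleted"`), `w_start`, `w_end` (0-based half-open on the
#'   pseudo-sequence; `NA` when deleted).
#' @export
liftover <- function(wpseq, z_interval, deletions = NULL) {
  env <- wpseq$source_interval
  s <- z_interval[1]
  e <- z_interval[2]
  if (s < env[1] || e > env[2] || s >= e) {
    rlang::abort("interval outside the ZTR envelope")
  }
  status <- "mapped"
  if (!is.null(deletions) && nrow(deletions) > 0L) {
    for (i in seq_len(nrow(deletions))) {
      ds <- deletions$start[i]
      de <- deletions$end[i]
      if (s >= ds && e <= de) {
        return(tibble::tibble(status = "deleted", w_start = NA_real_, w_end = NA_real_))
      }
      if (s < de && e > ds) { # partial overlap: truncate to the retained part
        status <- "partial"
        if (s >= ds) s <- de
        if (e <= de) e <- ds
      }
    }
    if (s >= e) {
      return(tibble::tibble(status = "deleted", w_start = NA_real_, w_end = NA_real_))
    }
  }
  tibble::tibble(
    status = status,
    w_start = z_to_w_pos(wpseq, s),
    w_end = z_to_w_pos(wpseq, e)
  )
}

# Map a 0-based Z coordinate to a 0-based W-pseudo coordinate. Offsets from
# applied indels take effect after the end of each indel's reference span;
# positions inside a consumed span are clamped to the span's mapped end.
z_to_w_pos <- function(wpseq, p) {
  env <- wpseq$source_interval
  cm <- wpseq$coord_map
  off <- 0L
  if (nrow(cm) > 0L) {
    before <- cm$z_pos <= p
    if (any(before)) off <- cm$cumulative_offset[max(which(before))]
  }
  w <- p - env[1] + off
  max(0, min(w, nchar(wpseq$sequence)))
}

#' Rederive variants by exact alignment of Z and W-pseudo sequences
#'
#' Globally aligns the reconstructed W pseudo-sequence back to its source Z
#' interval and reads off substitutions and left-normalized,
#' anchor-base-encoded indels (insertions as `ref = X, alt = X...`;
#' deletions as `ref = X..., alt = X`). With non-overlapping variants and
#' unambiguous indel context this is the inverse of
#' [build_w_pseudosequence()]; indels inside repeat runs are returned in
#' left-normalized form, which may differ from an un-normalized input
#' representation.
#'
#' @param z_seq reference sequence over the source interval (string).
#' @param w_seq reconstructed W pseudo-sequence (string).
#' @param offset 1-based position of the first `z_seq` base on the
#'   chromosome (so returned `pos` matches VCF coordinates); default 1.
#' @return Tibble `pos`, `ref`, `alt`, `vtype` sorted by position.
#' @export
rederive_variants <- function(z_seq, w_seq, offset = 1L) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(z_seq), Biostrings::DNAString(w_seq),
    type = "global",
    # mismatches are penalized above short gaps so a nearby deletion +
    # insertion pair is never re-expressed as a run of substitutions, while
    # a lone substitution still beats a 1-bp gap pair
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -3, baseOnly = TRUE
    ),
    gapOpening = 5, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  zpos <- 0L # 1-based position of last consumed z base
  rows <- list()
  i <- 1L
  while (i <= length(pa)) {
    if (pa[i] != "-" && sa[i] != "-") {
      zpos <- zpos + 1L
      if (pa[i] != sa[i]) {
        rows[[length(rows) + 1L]] <- list(
          pos = zpos, ref = pa[i], alt = sa[i], vtype = "SNP"
        )
      }
      i <- i + 1L
    } else if (pa[i] == "-") { # insertion in w
      j <- i
      while (j <= length(pa) && pa[j] == "-") j <- j + 1L
      ins <- paste(sa[i:(j - 1L)], collapse = "")
      anchor <- substr(z_seq, zpos, zpos)
      rows[[length(rows) + 1L]] <- list(
        pos = zpos, ref = anchor, alt = paste0(anchor, ins), vtype = "INDEL"
      )
      i <- j
    } else { # deletion from w
      j <- i
      while (j <= length(pa) && sa[j] == "-") j <- j + 1L
      del <- paste(pa[i:(j - 1L)], collapse = "")
      anchor <- substr(z_seq, zpos, zpos)
      rows[[length(rows) + 1L]] <- list(
        pos = zpos, ref = paste0(anchor, del), alt = anchor, vtype = "INDEL"
      )
      zpos <- zpos + nchar(del)
      i <- j
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(pos = integer(), ref = character(),
                          alt = character(), vtype = character()))
  }
  out <- left_normalize_variants(out, z_seq)
  out$pos <- out$pos + offset - 1L
  dplyr::arrange(out, .data$pos)
}

# Shift anchor-encoded indels left while the base preceding the event equals
# the last base of the inserted/deleted run (standard VCF left alignment).
left_normalize_variants <- function(variants, z_seq) {
  for (i in seq_len(nrow(variants))) {
    if (variants$vtype[i] != "INDEL") next
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    longer <- if (nchar(ref) > nchar(alt)) "del" else "ins"
    run <- if (longer == "del") substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
    while (pos > 1L) {
      cur <- substr(z_seq, pos, pos)
      if (cur != substr(run, nchar(run), nchar(run))) break
      run <- paste0(cur, substr(run, 1L, nchar(run) - 1L))
      pos <- pos - 1L
    }
    anchor <- substr(z_seq, pos, pos)
    if (longer == "del") {
      variants$ref[i] <- paste0(anchor, run)
      variants$alt[i] <- anchor
    } else {
      variants$ref[i] <- anchor
      variants$alt[i] <- paste0(anchor, run)
    }
    variants$pos[i] <- pos
  }
  variants
}
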