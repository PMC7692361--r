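# Nei-Gojobori (1986) counting of synonymous and nonsynonymous sites and
# substitutions, with Jukes-Cantor correction, plus parsimony polarization of
# Z/W gametolog divergence against an outgroup.

PERMS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
)

# Synonymous/nonsynonymous site fractions of one sense codon. Each of the 9
# single-base changes contributes 1/3 of a site to the synonymous class if it
# preserves the amino acid, otherwise (including changes to stops) to the
# nonsynonymous class, so the two classes always sum to 3 sites per codon.
codon_site_fractions <- function(codon) {
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa <- CODON_TABLE[[codon]]
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(DNA_BASES, bases[p])) {
      mut <- bases
      mut[p] <- alt
      if (CODON_TABLE[[paste(mut, collapse = "")]] == aa) syn <- syn + 1 / 3
    }
  }
  c(S = syn, N = 3 - syn)
}

# Substitution counts between two sense codons, averaged over all minimal
# mutational pathways; pathways passing through a stop codon are excluded.
# If every pathway is blocked by stops the average falls back to all
# pathways (rare; only possible for triple-difference codons).
codon_path_counts <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  ba <- strsplit(codon_a, "", fixed = TRUE)[[1]]
  bb <- strsplit(codon_b, "", fixed = TRUE)[[1]]
  diff_pos <- which(ba != bb)
  k <- length(diff_pos)
  paths <- PERMS[[as.character(k)]]
  tally <- function(order, respect_stops) {
    cur <- ba
    sd <- 0
    nd <- 0
    for (p in diff_pos[order]) {
      nxt <- cur
      nxt[p] <- bb[p]
      cod_cur <- paste(cur, collapse = "")
      cod_nxt <- paste(nxt, collapse = "")
      if (respect_stops && CODON_TABLE[[cod_nxt]] == "*" && cod_nxt != codon_b) {
        return(NULL)
      }
      if (CODON_TABLE[[cod_cur]] == CODON_TABLE[[cod_nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- purrr::compact(lapply(paths, tally, respect_stops = TRUE))
  if (length(counts) == 0L) {
    counts <- lapply(paths, tally, respect_stops = FALSE)
  }
  Reduce(`+`, counts) / length(counts)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_) # saturated
  -3 / 4 * log(1 - 4 / 3 * p)
}

codon_is_countable <- function(codon) {
  nchar(codon) == 3L && !grepl("[^ACGT]", codon)
}

check_no_stops <- function(codons, label) {
  stops <- which(is_stop_codon(codons))
  if (length(stops) > 0L) {
    rlang::abort(paste0(
      "stop codon in ", label, " at codon position ",
      paste(head(stops, 5), collapse = ", ")
    ))
  }
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (each of the
#' nine possible single-base changes contributes 1/3 site; changes creating a
#' stop codon count as nonsynonymous, so `S + N = 3 * n_codons` exactly), and
#' synonymous/nonsynonymous differences `sd`/`nd` averaged over all minimal
#' mutational pathways between differing codons, excluding pathways through
#' stop codons. Proportions `pS = sd/S` and `pN = nd/N` are Jukes-Cantor
#' corrected, `d = -3/4 log(1 - 4/3 p)`; a proportion at or beyond 3/4 is
#' flagged saturated and its distance reported as `NA`.
#'
#' Codon columns containing gaps or ambiguous bases in either sequence are
#' excluded from counting; an in-frame stop codon in a counted column is an
#' error.
#'
#' @param seq_a,seq_b equal-length in-frame nucleotide strings.
#' @return One-row tibble with `n_codons`, `S`, `N`, `sd`, `nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega`, `omega_defined`, `saturated`.
#' @examples
#' ng86_pairwise("ATGAAA", "ATGAAG")
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) rlang::abort("sequences must be equal length")
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  keep <- vapply(ca, codon_is_countable, logical(1)) &
    vapply(cb, codon_is_countable, logical(1))
  ca <- ca[keep]
  cb <- cb[keep]
  check_no_stops(ca, "seq_a")
  check_no_stops(cb, "seq_b")
  n_codons <- length(ca)
  sites_a <- vapply(ca, codon_site_fractions, numeric(2))
  sites_b <- vapply(cb, codon_site_fractions, numeric(2))
  S <- (sum(sites_a["S", ]) + sum(sites_b["S", ])) / 2
  N <- (sum(sites_a["N", ]) + sum(sites_b["N", ])) / 2
  counts <- mapply(codon_path_counts, ca, cb)
  sd_tot <- if (n_codons) sum(counts["sd", ]) else 0
  nd_tot <- if (n_codons) sum(counts["nd", ]) else 0
  pS <- if (S > 0) sd_tot / S else NA_real_
  pN <- if (N > 0) nd_tot / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  saturated <- (!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)
  omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
  tibble::tibble(
    n_codons = n_codons, S = S, N = N, sd = sd_tot, nd = nd_tot,
    pS = pS, pN = pN, dS = dS, dN = dN,
    omega = if (omega_defined) dN / dS else NA_real_,
    omega_defined = omega_defined, saturated = saturated
  )
}

#' Branch-specific dN/dS for a Z/W gametolog pair with an outgroup
#'
#' Polarizes each codon at which the Z and W copies differ by parsimony
#' against an outgroup: the copy matching the outgroup is taken as ancestral
#' and the substitutions are assigned to the other copy's branch. Codons at
#' which all three sequences differ cannot be polarized and are tallied
#' separately (a warning is raised when they exceed 20% of the Z/W-differing
#' codons). Site counts use the Nei-Gojobori fractions averaged over the Z
#' and W sequences and are shared by both branches.
#'
#' @param alignment named character vector of aligned in-frame sequences (or
#'   the object returned by [simulate_codon_alignment()]).
#' @param z,w,outgroup taxon names present in `alignment`.
#' @return A `ztr_branch_rates` tibble with one row per branch (`Z`, `W`):
#'   `sd`, `nd`, `S`, `N`, `pS`, `pN`, `dS`, `dN`, `omega`, `omega_defined`.
#'   Attributes carry the unpolarized tallies; see [glance()].
#' @export
branch_rates <- function(alignment, z = "Z", w = "W", outgroup = "outgroup") {
  seqs <- as_alignment_vector(alignment)
  missing <- setdiff(c(z, w, outgroup), names(seqs))
  if (length(missing) > 0L) {
    rlang::abort(paste0("taxa not in alignment: ", paste(missing, collapse = ", ")))
  }
  cz <- split_codons(toupper(seqs[[z]]))
  cw <- split_codons(toupper(seqs[[w]]))
  co <- split_codons(toupper(seqs[[outgroup]]))
  if (length(unique(c(length(cz), length(cw), length(co)))) != 1L) {
    rlang::abort("aligned sequences must have equal length")
  }
  keep <- vapply(cz, codon_is_countable, logical(1)) &
    vapply(cw, codon_is_countable, logical(1)) &
    vapply(co, codon_is_countable, logical(1))
  cz <- cz[keep]
  cw <- cw[keep]
  co <- co[keep]
  check_no_stops(cz, "Z sequence")
  check_no_stops(cw, "W sequence")
  check_no_stops(co, "outgroup sequence")

  sites_z <- vapply(cz, codon_site_fractions, numeric(2))
  sites_w <- vapply(cw, codon_site_fractions, numeric(2))
  S <- (sum(sites_z["S", ]) + sum(sites_w["S", ])) / 2
  N <- (sum(sites_z["N", ]) + sum(sites_w["N", ])) / 2

  tallies <- list(
    Z = c(sd = 0, nd = 0), W = c(sd = 0, nd = 0),
    unpolarized = c(sd = 0, nd = 0)
  )
  n_diff <- 0L
  n_unpolarized <- 0L
  for (i in seq_along(cz)) {
    if (cz[i] == cw[i]) next
    n_diff <- n_diff + 1L
    if (cw[i] == co[i]) {
      tallies$Z <- tallies$Z + codon_path_counts(cw[i], cz[i])
    } else if (cz[i] == co[i]) {
      tallies$W <- tallies$W + codon_path_counts(cz[i], cw[i])
    } else {
      n_unpolarized <- n_unpolarized + 1L
      tallies$unpolarized <- tallies$unpolarized + codon_path_counts(cz[i], cw[i])
    }
  }
  if (n_diff > 0L && n_unpolarized / n_diff > 0.2) {
    rlang::warn(sprintf(
      "%d of %d Z/W-differing codons could not be polarized; branch assignment unreliable",
      n_unpolarized, n_diff
    ))
  }

  branch_row <- function(branch) {
    cnt <- tallies[[branch]]
    pS <- if (S > 0) cnt[["sd"]] / S else NA_real_
    pN <- if (N > 0) cnt[["nd"]] / N else NA_real_
    dS <- jc_correct(pS)
    dN <- jc_correct(pN)
    omega_defined <- !is.na(dS) && !is.na(dN) && dS > 0
    tibble::tibble(
      branch = branch, sd = cnt[["sd"]], nd = cnt[["nd"]], S = S, N = N,
      pS = pS, pN = pN, dS = dS, dN = dN,
      omega = if (omega_defined) dN / dS else NA_real_,
      omega_defined = omega_defined
    )
  }
  out <- dplyr::bind_rows(branch_row("Z"), branch_row("W"))
  structure(
    out,
    class = c("ztr_branch_rates", class(out)),
    n_codons = length(cz),
    n_zw_differing = n_diff,
    n_unpolarized = n_unpolarized,
    unpolarized_sd = tallies$unpolarized[["sd"]],
    unpolarized_nd = tallies$unpolarized[["nd"]]
  )
}

as_alignment_vector <- function(alignment) {
  if (inherits(alignment, "ztr_codon_alignment")) {
    return(alignment$sequences)
  }
  if (is.character(alignment) && !is.null(names(alignment))) {
    return(alignment)
  }
  if (is.data.frame(alignment) && all(c("name", "sequence") %in% names(alignment))) {
    return(setNames(alignment$sequence, alignment$name))
  }
  rlang::abort("alignment must be a named character vector, a (name, sequence) data frame, or a ztr_codon_alignment")
}

#' @export
tidy.ztr_branch_rates <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.ztr_branch_rates <- function(x, ...) {
  tibble::tibble(
    n_codons = attr(x, "n_codons"),
    n_zw_differing = attr(x, "n_zw_differing"),
    n_unpolarized = attr(x, "n_unpolarized"),
    unpolarized_sd = attr(x, "unpolarized_sd"),
    unpolarized_nd = attr(x, "unpolarized_nd")
  )
}
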