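# Seed-deterministic synthetic data with planted truth: reference + genes,
# per-sex depth tables and variant records, codon alignments evolved under
# branch-specific omega, and expression tables.

REGION_CLASSES <- c("AUTOSOME_LIKE", "HEMIZYGOUS_Z", "PAR", "ZTR", "Z_DUP")

#' Simulation layout
#'
#' Describes one synthetic chromosome: a non-overlapping tiling of region
#' classes, W-deletions nested inside ZTRs, and gene models. All intervals
#' are 0-based half-open.
#'
#' @param chrom_name chromosome name.
#' @param chrom_length length in bp.
#' @param window_size analysis window width in bp; default 50,000.
#' @param regions tibble `start`, `end`, `class` tiling
#'   `[0, chrom_length)`; classes from
#'   `AUTOSOME_LIKE, HEMIZYGOUS_Z, PAR, ZTR, Z_DUP`.
#' @param w_deletions tibble `start`, `end`; each interval must lie inside
#'   exactly one ZTR region.
#' @param genes gene model tibble from [gene_models()].
#' @return A validated `ztr_sim_layout` list.
#' @export
sim_layout <- function(chrom_name, chrom_length, window_size = 50000L,
                       regions, w_deletions = NULL, genes = NULL) {
  regions <- dplyr::arrange(tibble::as_tibble(regions), .data$start)
  w_deletions <- tibble::as_tibble(w_deletions %||%
                                     tibble::tibble(start = numeric(), end = numeric()))
  genes <- genes %||% gene_models(character(), numeric(), numeric())

  if (!all(regions$class %in% REGION_CLASSES)) {
    rlang::abort("unknown region class in layout")
  }
  if (regions$start[1] != 0 || regions$end[nrow(regions)] != chrom_length ||
      (nrow(regions) > 1 && any(regions$start[-1] != regions$end[-nrow(regions)]))) {
    rlang::abort("regions must tile [0, chrom_length) without gaps or overlap")
  }
  ztrs <- regions[regions$class == "ZTR", ]
  for (i in seq_len(nrow(w_deletions))) {
    inside <- ztrs$start <= w_deletions$start[i] & ztrs$end >= w_deletions$end[i]
    if (sum(inside) != 1L) {
      rlang::abort("every w_deletion must be contained in exactly one ZTR region")
    }
  }
  if (nrow(genes) > 0L && any(genes$start < 0 | genes$end > chrom_length)) {
    rlang::abort("gene outside chromosome bounds")
  }
  structure(
    list(chrom_name = chrom_name, chrom_length = as.integer(chrom_length),
         window_size = as.integer(window_size), regions = regions,
         w_deletions = w_deletions, genes = genes),
    class = "ztr_sim_layout"
  )
}

#' Simulation parameters
#'
#' @param haploid_depth expected reads per site per chromosome copy;
#'   default 15.
#' @param zw_divergence Z-W divergence sites per bp inside a ZTR;
#'   default 0.002 (a young transposition).
#' @param indel_rate indel events per bp on the W copy of a ZTR;
#'   default 1e-5.
#' @param background_het background heterozygosity per bp, both sexes;
#'   default 1e-4.
#' @param dup_psv_rate paralogous sequence variant sites per bp inside a
#'   Z-linked duplication (seen in both sexes); default 1e-3.
#' @param fail_fraction fraction of emitted variant records drawn to
#'   violate exactly one hard-filter criterion; default 0.05.
#' @param overdispersion negative-binomial overdispersion of site depth
#'   (0 = Poisson, the default).
#' @param af_beta_shape shape of the symmetric Beta mixing the
#'   heterozygous allele fraction around 0.5; default 50.
#' @param seed integer seed fully determining all outputs.
#' @return A `ztr_sim_params` list.
#' @export
sim_params <- function(haploid_depth = 15, zw_divergence = 0.002,
                       indel_rate = 1e-5, background_het = 1e-4,
                       dup_psv_rate = 1e-3, fail_fraction = 0.05,
                       overdispersion = 0, af_beta_shape = 50, seed = 1L) {
  rates <- c(haploid_depth, zw_divergence, indel_rate, background_het,
             dup_psv_rate, fail_fraction, overdispersion)
  if (any(rates < 0)) rlang::abort("all rates must be >= 0")
  structure(
    list(haploid_depth = haploid_depth, zw_divergence = zw_divergence,
         indel_rate = indel_rate, background_het = background_het,
         dup_psv_rate = dup_psv_rate, fail_fraction = fail_fraction,
         overdispersion = overdispersion, af_beta_shape = af_beta_shape,
         seed = as.integer(seed)),
    class = "ztr_sim_params"
  )
}

#' Default synthetic chromosome layout
#'
#' A 10 Mb Z-like chromosome of 200 windows of 50 kb: a terminal 0.5 Mb
#' PAR, hemizygous-Z background, a 1.3 Mb ZTR carrying a 150 kb internal
#' W-deletion and nine genes (two intact survivors, five genes wholly
#' inside the deletion, two straddling its boundaries — mirroring the gene
#' inventory of a young avian ZTR), and a 100 kb Z-linked duplication
#' spanning one gene.
#'
#' @return A `ztr_sim_layout`.
#' @export
default_sim_layout <- function() {
  regions <- tibble::tibble(
    start = c(0, 5e5, 5.5e6, 6.8e6, 8.0e6, 8.1e6),
    end = c(5e5, 5.5e6, 6.8e6, 8.0e6, 8.1e6, 1e7),
    class = c("PAR", "HEMIZYGOUS_Z", "ZTR", "HEMIZYGOUS_Z", "Z_DUP", "HEMIZYGOUS_Z")
  )
  w_deletions <- tibble::tibble(start = 6.0e6, end = 6.15e6)
  gene_at <- function(gene_start) {
    # 10 kb gene with a single 1.2 kb CDS starting 2 kb in
    cds_start <- gene_start + 2000
    tibble::tibble(start = cds_start, end = cds_start + 1200)
  }
  starts <- c(
    ANXA1 = 5.60e6, ALDH1A1 = 5.75e6, RORB = 5.995e6,
    ZFAND5 = 6.01e6, TRPM3 = 6.03e6, TMEM2 = 6.05e6,
    GDA = 6.07e6, C9orf85 = 6.09e6, TMC1 = 6.145e6,
    YTHDC2 = 8.02e6
  )
  genes <- gene_models(
    name = names(starts),
    start = unname(starts),
    end = unname(starts) + 1e4,
    strand = c("+", "-", "+", "+", "+", "-", "+", "+", "+", "+"),
    cds = lapply(unname(starts), gene_at)
  )
  sim_layout("chrZ_sim", 1e7, 50000L, regions, w_deletions, genes)
}

region_copy_number <- function(layout, sex) {
  cls <- layout$regions$class
  base <- c(AUTOSOME_LIKE = 2, PAR = 2, HEMIZYGOUS_Z = 2, ZTR = 2, Z_DUP = 2)
  cn <- base[cls]
  if (sex == "female") {
    cn[cls == "HEMIZYGOUS_Z"] <- 1
  } else {
    cn[cls == "Z_DUP"] <- 4
  }
  unname(cn)
}

# split the region tiling into (start, end, copy) segments for one sex,
# carving female W-deletions (copy 1) out of ZTRs
copy_segments <- function(layout, sex) {
  segs <- tibble::tibble(
    start = layout$regions$start, end = layout$regions$end,
    copy = region_copy_number(layout, sex)
  )
  if (sex == "female" && nrow(layout$w_deletions) > 0L) {
    for (i in seq_len(nrow(layout$w_deletions))) {
      ds <- layout$w_deletions$start[i]
      de <- layout$w_deletions$end[i]
      hit <- which(segs$start <= ds & segs$end >= de)[1]
      before <- segs[hit, ]
      pieces <- tibble::tibble(
        start = c(before$start, ds, de),
        end = c(ds, de, before$end),
        copy = c(before$copy, 1, before$copy)
      )
      pieces <- pieces[pieces$end > pieces$start, ]
      segs <- dplyr::arrange(
        dplyr::bind_rows(segs[-hit, ], pieces), .data$start
      )
    }
  }
  segs
}

#' Generate the reference and planted truth for a simulated chromosome
#'
#' Draws the reference sequence, rewrites each gene's CDS as a clean open
#' reading frame, and plants the fixed sequence features the per-sex
#' emitters share: Z-W divergence SNPs and W indels inside ZTRs (outside
#' W-deletions) and paralogous sequence variants inside Z-linked
#' duplications. Truth gene fates are derived from the planted deletions
#' and variants. Everything is a deterministic function of
#' `params$seed`.
#'
#' @param layout a [sim_layout()].
#' @param params a [sim_params()].
#' @return A `ztr_sim` object: `reference` (string), `layout`, `params`,
#'   and `truth` (window labels, regions, W-deletions, shared variants,
#'   gene fates).
#' @export
simulate_reference <- function(layout, params = sim_params()) {
  sim <- with_seed(sub_seed(params$seed, "reference"), {
    ref <- random_dna(layout$chrom_length)
    # overwrite CDS with clean ORFs: ATG + non-stop codons + TAA
    for (i in seq_len(nrow(layout$genes))) {
      cds <- layout$genes$cds[[i]]
      len <- sum(cds$end - cds$start)
      if (len %% 3L != 0L) rlang::abort("CDS length must be divisible by 3")
      n_mid <- len / 3L - 2L
      sense <- setdiff(names(CODON_TABLE)[unlist(CODON_TABLE) != "*"], "ATG")
      orf <- paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""), "TAA")
      if (layout$genes$strand[i] == "-") orf <- revcomp(orf)
      offset <- 0L
      for (j in order(cds$start)) {
        seg_len <- cds$end[j] - cds$start[j]
        substr(ref, cds$start[j] + 1L, cds$end[j]) <-
          substr(orf, offset + 1L, offset + seg_len)
        offset <- offset + seg_len
      }
    }
    shared <- plant_shared_variants(ref, layout, params)
    list(reference = ref, shared = shared)
  })
  truth <- list(
    window_labels = truth_window_labels(layout),
    regions = layout$regions,
    w_deletions = layout$w_deletions,
    shared_variants = sim$shared
  )
  out <- structure(
    list(reference = sim$reference, layout = layout, params = params,
         truth = truth),
    class = "ztr_sim"
  )
  out$truth$gene_fates <- truth_gene_fates(out)
  out
}

# fixed sequence features shared across samples (drawn once per seed)
plant_shared_variants <- function(ref, layout, params) {
  draw_positions <- function(intervals, rate) {
    unlist(lapply(seq_len(nrow(intervals)), function(i) {
      len <- intervals$end[i] - intervals$start[i]
      n <- rpois(1L, rate * len)
      if (n == 0L) return(integer(0))
      sort(sample.int(len, min(n, len))) + intervals$start[i] # 1-based
    }))
  }
  ztr_minus_del <- subtract_intervals(
    layout$regions[layout$regions$class == "ZTR", c("start", "end")],
    layout$w_deletions
  )
  dup <- layout$regions[layout$regions$class == "Z_DUP", c("start", "end")]

  snp_at <- function(pos, provenance) {
    if (length(pos) == 0L) {
      return(tibble::tibble(pos = integer(), ref = character(), alt = character(),
                            vtype = character(), provenance = character()))
    }
    ref_allele <- substring(ref, pos, pos)
    alt_allele <- vapply(ref_allele, function(r) sample(setdiff(DNA_BASES, r), 1L),
                         character(1), USE.NAMES = FALSE)
    tibble::tibble(pos = as.integer(pos), ref = ref_allele, alt = alt_allele,
                   vtype = "SNP", provenance = provenance)
  }
  div <- snp_at(draw_positions(ztr_minus_del, params$zw_divergence), "divergence")
  psv <- snp_at(draw_positions(dup, params$dup_psv_rate), "psv")

  ind_pos <- draw_positions(ztr_minus_del, params$indel_rate)
  ind <- lapply(ind_pos, function(p) {
    is_ins <- runif(1) < 0.5
    len <- sample(1:3, 1L)
    anchor <- substring(ref, p, p)
    if (is_ins) {
      tibble::tibble(pos = as.integer(p), ref = anchor,
                     alt = paste0(anchor, random_dna(len)),
                     vtype = "INDEL", provenance = "indel_divergence")
    } else {
      tibble::tibble(pos = as.integer(p),
                     ref = substring(ref, p, p + len),
                     alt = anchor,
                     vtype = "INDEL", provenance = "indel_divergence")
    }
  })
  ind <- bind_or_template(ind, div[0, ])
  out <- dplyr::arrange(dplyr::bind_rows(div, psv, ind), .data$pos)
  out <- out[!duplicated(out$pos), ]
  if (nrow(out) > 0L) {
    out <- left_normalize_variants(out, ref)
    out <- dplyr::arrange(out, .data$pos)
    out <- out[!duplicated(out$pos), ]
  }
  out
}

subtract_intervals <- function(intervals, holes) {
  if (nrow(intervals) == 0L) return(intervals)
  out <- intervals
  for (i in seq_len(nrow(holes))) {
    nxt <- list()
    for (j in seq_len(nrow(out))) {
      s <- out$start[j]; e <- out$end[j]
      hs <- holes$start[i]; he <- holes$end[i]
      if (he <= s || hs >= e) {
        nxt[[length(nxt) + 1L]] <- tibble::tibble(start = s, end = e)
      } else {
        if (hs > s) nxt[[length(nxt) + 1L]] <- tibble::tibble(start = s, end = hs)
        if (he < e) nxt[[length(nxt) + 1L]] <- tibble::tibble(start = he, end = e)
      }
    }
    out <- dplyr::bind_rows(nxt)
  }
  out
}

truth_window_labels <- function(layout) {
  wsize <- layout$window_size
  n_win <- layout$chrom_length %/% wsize
  start <- (seq_len(n_win) - 1L) * wsize
  mid <- start + wsize / 2
  lab <- vapply(mid, function(p) {
    layout$regions$class[layout$regions$start <= p & layout$regions$end > p][1]
  }, character(1))
  # windows inside a female W-deletion show the hemizygous signature
  for (i in seq_len(nrow(layout$w_deletions))) {
    inside <- start >= layout$w_deletions$start[i] &
      (start + wsize) <= layout$w_deletions$end[i]
    lab[inside] <- "HEMIZYGOUS_Z"
  }
  tibble::tibble(chrom = layout$chrom_name, start = start, end = start + wsize,
                 label = lab)
}

# Truth gene fates from planted deletions and shared variants: deletion
# containment first, then frameshift / premature-stop assessment on the
# constructed W copy.
truth_gene_fates <- function(sim) {
  layout <- sim$layout
  genes <- layout$genes
  ztrs <- layout$regions[layout$regions$class == "ZTR", ]
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    in_ztr <- any(ztrs$start <= g$start & ztrs$end >= g$end)
    if (!in_ztr) next
    env <- ztrs[ztrs$start <= g$start & ztrs$end >= g$end, ][1, ]
    fate <- NULL
    for (j in seq_len(nrow(layout$w_deletions))) {
      ds <- layout$w_deletions$start[j]; de <- layout$w_deletions$end[j]
      if (g$start >= ds && g$end <= de) { fate <- "deleted"; break }
      if (g$start < de && g$end > ds) { fate <- "partial_deletion"; break }
    }
    if (is.null(fate)) {
      vars <- sim$truth$shared_variants
      vars <- vars[vars$provenance %in% c("divergence", "indel_divergence") &
                     vars$pos > env$start & vars$pos <= env$end, ]
      wp <- build_w_pseudosequence(sim$reference, c(env$start, env$end), vars)
      fate_row <- suppressWarnings(assess_orf(g, sim$reference, wp))
      fate <- fate_row$fate
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(name = g$name, fate = fate)
  }
  bind_or_template(rows, tibble::tibble(name = character(), fate = character()))
}

#' Simulate a per-site depth table for one sex
#'
#' Site depth is Poisson with mean `copy_number * haploid_depth / 2 * 2`
#' per copy, i.e. `c * D` where `c` is the sample's copy number at the
#' site: two everywhere for a diploid-like state, one for hemizygous
#' females (and female W-deletions inside ZTRs), four for males in a
#' Z-linked duplication. Only sites with depth >= 1 are emitted
#' (samtools-depth dialect). When `overdispersion > 0` a gamma-Poisson
#' (negative binomial) with that dispersion is used instead.
#'
#' @param sim a `ztr_sim` from [simulate_reference()].
#' @param sex `"female"` or `"male"`.
#' @return Tibble `chrom`, `pos` (1-based), `depth`.
#' @export
simulate_depth <- function(sim, sex) {
  stopifnot_scalar_sex(sex)
  layout <- sim$layout
  params <- sim$params
  segs <- copy_segments(layout, sex)
  with_seed(sub_seed(params$seed, paste0("depth_", sex)), {
    pieces <- lapply(seq_len(nrow(segs)), function(i) {
      len <- as.integer(segs$end[i] - segs$start[i])
      lam <- segs$copy[i] * params$haploid_depth
      d <- if (params$overdispersion > 0) {
        size <- 1 / params$overdispersion
        rpois(len, lam * stats::rgamma(len, shape = size, rate = size))
      } else {
        rpois(len, lam)
      }
      keep <- d > 0L
      list(pos = as.integer(segs$start[i]) + which(keep), depth = d[keep])
    })
    tibble::tibble(
      chrom = layout$chrom_name,
      pos = unlist(lapply(pieces, `[[`, "pos")),
      depth = unlist(lapply(pieces, `[[`, "depth"))
    )
  })
}

#' Simulate variant records for one sex
#'
#' Emits heterozygous records: fixed Z-W divergence SNPs and W indels
#' (female only, inside ZTRs outside W-deletions), paralogous sequence
#' variants (both sexes, inside Z-linked duplications), and background
#' polymorphism everywhere (both sexes, sex-specific positions). Allele
#' depths are drawn at the site's copy-number-scaled depth with the
#' alternate fraction mixed Beta(`af_beta_shape`, `af_beta_shape`) around
#' 0.5. Annotation fields are drawn from passing distributions except for
#' a `fail_fraction` of records that each violate exactly one hard-filter
#' criterion (recorded in `planted_fail`).
#'
#' @inheritParams simulate_depth
#' @return Variant tibble (see [hard_filter()]) with extra truth columns
#'   `provenance` and `planted_fail`.
#' @export
simulate_variants <- function(sim, sex) {
  stopifnot_scalar_sex(sex)
  layout <- sim$layout
  params <- sim$params
  shared <- sim$truth$shared_variants
  own <- if (sex == "female") {
    shared
  } else {
    shared[shared$provenance == "psv", , drop = FALSE]
  }
  with_seed(sub_seed(params$seed, paste0("variants_", sex)), {
    # sex-specific background polymorphism over the whole chromosome
    n_bg <- rpois(1L, params$background_het * layout$chrom_length)
    bg_pos <- sort(sample.int(layout$chrom_length, n_bg))
    bg_ref <- substring(sim$reference, bg_pos, bg_pos)
    bg_alt <- vapply(bg_ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                     character(1), USE.NAMES = FALSE)
    bg <- tibble::tibble(pos = as.integer(bg_pos), ref = bg_ref, alt = bg_alt,
                         vtype = "SNP", provenance = paste0("polymorphism_", sex))
    rec <- dplyr::arrange(dplyr::bind_rows(own, bg), .data$pos)
    rec <- rec[!duplicated(rec$pos), ]
    n <- nrow(rec)

    # copy-number-scaled site depth for allele depths
    segs <- copy_segments(layout, sex)
    copy_at <- vapply(rec$pos, function(p) {
      segs$copy[segs$start < p & segs$end >= p][1]
    }, numeric(1))
    dp <- pmax(1L, rpois(n, copy_at * params$haploid_depth))
    af_p <- rbeta(n, params$af_beta_shape, params$af_beta_shape)
    ad_alt <- rbinom(n, dp, af_p)
    rec$ad_ref <- dp - ad_alt
    rec$ad_alt <- ad_alt
    rec$allele_fraction <- ad_alt / dp

    ann <- passing_annotations(n)
    fail_idx <- which(runif(n) < params$fail_fraction)
    rec$planted_fail <- NA_character_
    for (i in fail_idx) {
      crit <- sample(HARD_FILTER_RULES$annotation, 1L)
      ann[[crit]][i] <- failing_value(crit)
      rec$planted_fail[i] <- crit
    }
    rec <- dplyr::bind_cols(rec, ann)
    rec$chrom <- layout$chrom_name
    rec$sex <- sex
    dplyr::relocate(rec, "chrom", "pos", "ref", "alt", "vtype")
  })
}

passing_annotations <- function(n) {
  tibble::tibble(
    FS = runif(n, 0, 9),
    QD = runif(n, 5, 30),
    MQ = runif(n, 55, 60),
    SOR = runif(n, 0.2, 1.2),
    MQRankSum = runif(n, -1, 1),
    ReadPosRankSum = runif(n, -4, 4)
  )
}

failing_value <- function(criterion) {
  switch(criterion,
    FS = runif(1, 10.5, 60),
    QD = runif(1, 0, 1.9),
    MQ = runif(1, 20, 49.5),
    SOR = runif(1, 1.55, 4),
    MQRankSum = runif(1, -5, -1.55),
    ReadPosRankSum = runif(1, -15, -8.5)
  )
}

#' Simulate a codon alignment under branch-specific dN/dS
#'
#' Evolves a stop-free ancestral codon sequence along each branch of a
#' small tree (default: outgroup plus a Z/W gametolog pair radiating from
#' the common ancestor). Mutation events are proposed at rate
#' `length * 3 * n_codons` per branch; a proposal is rejected if it
#' creates a stop codon, accepted if synonymous, and accepted with
#' probability `omega` if nonsynonymous (for `omega > 1` the synonymous
#' acceptance is scaled down instead). Within a branch, at most one
#' substitution is placed per codon, so parsimony polarization against the
#' outgroup is exact at the low divergences simulated.
#'
#' @param n_codons alignment length in codons; below 50 a warning is
#'   raised (downstream counting estimates are unstable).
#' @param branches tibble `name`, `length` (expected neutral substitutions
#'   per nucleotide site), `omega` (>= 0); every branch radiates from the
#'   root ancestor. Defaults to `outgroup`, `Z`, `W`.
#' @param allow_homoplasy when `FALSE` (default) substitutions are also
#'   restricted to codons untouched on every other branch, so the
#'   alignment is homoplasy-free and parsimony polarization against the
#'   outgroup is exact; set `TRUE` to let branches hit shared codons
#'   (yielding occasionally unpolarizable or convergent codons).
#' @param seed integer seed.
#' @return A `ztr_codon_alignment`: `sequences` (named, gap-free,
#'   in-frame), `truth` (per branch: realized synonymous `sd_true` and
#'   nonsynonymous `nd_true` substitution counts), `n_codons`.
#' @export
simulate_codon_alignment <- function(n_codons,
                                     branches = tibble::tibble(
                                       name = c("outgroup", "Z", "W"),
                                       length = c(0.10, 0.04, 0.04),
                                       omega = c(0.5, 0.5, 0.5)
                                     ),
                                     allow_homoplasy = FALSE, seed = 1L) {
  branches <- tibble::as_tibble(branches)
  if (any(branches$omega < 0) || any(branches$length < 0)) {
    rlang::abort("branch lengths and omega must be >= 0")
  }
  if (n_codons < 50) rlang::warn("fewer than 50 codons: counting estimates are unstable")
  with_seed(sub_seed(seed, "codon"), {
    sense <- names(CODON_TABLE)[unlist(CODON_TABLE) != "*"]
    ancestor <- sample(sense, n_codons, replace = TRUE)
    tree_hit <- logical(n_codons)
    evolve <- function(codons, len, omega) {
      n_events <- rpois(1L, len * 3 * n_codons)
      sd <- 0L
      nd <- 0L
      hit <- logical(n_codons)
      acc_syn <- min(1, 1 / max(omega, 1))
      acc_non <- min(1, omega)
      for (e in seq_len(n_events)) {
        ci <- sample.int(n_codons, 1L)
        if (hit[ci] || (!allow_homoplasy && tree_hit[ci])) next
        p <- sample.int(3L, 1L)
        old <- codons[ci]
        bases <- strsplit(old, "", fixed = TRUE)[[1]]
        bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
        new <- paste(bases, collapse = "")
        if (CODON_TABLE[[new]] == "*") next
        syn <- CODON_TABLE[[new]] == CODON_TABLE[[old]]
        acc <- if (syn) acc_syn else acc_non
        if (runif(1) < acc) {
          codons[ci] <- new
          hit[ci] <- TRUE
          if (syn) sd <- sd + 1L else nd <- nd + 1L
        }
      }
      tree_hit <<- tree_hit | hit
      list(codons = codons, sd = sd, nd = nd)
    }
    seqs <- list()
    truth <- branches
    truth$sd_true <- 0L
    truth$nd_true <- 0L
    for (i in seq_len(nrow(branches))) {
      ev <- evolve(ancestor, branches$length[i], branches$omega[i])
      seqs[[branches$name[i]]] <- paste(ev$codons, collapse = "")
      truth$sd_true[i] <- ev$sd
      truth$nd_true[i] <- ev$nd
    }
    structure(
      list(
        sequences = unlist(seqs),
        ancestor = paste(ancestor, collapse = ""),
        truth = truth,
        n_codons = n_codons
      ),
      class = "ztr_codon_alignment"
    )
  })
}

#' Simulate a long-format expression table
#'
#' Draws replicate TPM values around per-(gene, tissue, sex) means on a
#' log-normal scale. Genes listed in `biased_genes` get a female-gonad
#' mean `bias_fold` times their base mean; all other conditions share the
#' base mean.
#'
#' @param genes character vector of gene names.
#' @param biased_genes subset of `genes` with ovary-biased expression.
#' @param tissues tissue names; must include `gonad_tissue`.
#' @param species species names; default one synthetic species.
#' @param n_replicates replicates per condition; default 2.
#' @param base_tpm base mean TPM; default 20.
#' @param bias_fold female-gonad fold elevation for biased genes;
#'   default 10.
#' @param cv log-scale coefficient of variation across replicates;
#'   default 0.2.
#' @param gonad_tissue name of the gonad tissue; default `"gonad"`.
#' @param seed integer seed.
#' @return Long tibble `species`, `tissue`, `sex`, `replicate`, `gene`,
#'   `tpm`.
#' @export
simulate_expression <- function(genes, biased_genes = character(),
                                tissues = c("gonad", "brain", "liver", "spleen"),
                                species = "species_sim", n_replicates = 2L,
                                base_tpm = 20, bias_fold = 10, cv = 0.2,
                                gonad_tissue = "gonad", seed = 1L) {
  if (!gonad_tissue %in% tissues) {
    rlang::abort("tissues must include the female-gonad tissue")
  }
  grid <- tidyr::expand_grid(
    species = species, tissue = tissues, sex = c("female", "male"),
    replicate = seq_len(n_replicates), gene = genes
  )
  with_seed(sub_seed(seed, "expression"), {
    mu <- rep(base_tpm, nrow(grid))
    biased <- grid$gene %in% biased_genes &
      grid$tissue == gonad_tissue & grid$sex == "female"
    mu[biased] <- base_tpm * bias_fold
    grid$tpm <- mu * exp(rnorm(nrow(grid), -cv^2 / 2, cv))
    grid
  })
}
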