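# Shared fixtures: a small fast layout, record constructors, and
# independent oracles.

# 2 Mb chromosome, 40 windows of 50 kb: PAR, hemizygous background, a
# 0.6 Mb ZTR with a 150 kb internal W-deletion and three genes, a 100 kb
# Z-linked duplication.
small_layout <- function() {
  regions <- tibble::tibble(
    start = c(0, 2e5, 8e5, 1.4e6, 1.7e6, 1.8e6),
    end = c(2e5, 8e5, 1.4e6, 1.7e6, 1.8e6, 2e6),
    class = c("PAR", "HEMIZYGOUS_Z", "ZTR", "HEMIZYGOUS_Z", "Z_DUP", "HEMIZYGOUS_Z")
  )
  w_deletions <- tibble::tibble(start = 1.0e6, end = 1.15e6)
  gene_cds <- function(s) tibble::tibble(start = s + 1000, end = s + 1000 + 600)
  starts <- c(geneA = 8.5e5, geneB = 0.994e6, geneC = 1.05e6)
  genes <- gene_models(
    name = names(starts), start = unname(starts), end = unname(starts) + 8000,
    strand = c("+", "+", "-"), cds = lapply(unname(starts), gene_cds)
  )
  sim_layout("chrZ_t", 2e6, 50000L, regions, w_deletions, genes)
}

# one variant record row with passing annotations unless overridden
make_record <- function(pos, ref = "A", alt = "G", vtype = "SNP",
                        FS = 3, QD = 20, MQ = 58, SOR = 1.0,
                        MQRankSum = 0, ReadPosRankSum = 0,
                        allele_fraction = 0.5, chrom = "chr1",
                        sex = "female") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, vtype = vtype,
    FS = FS, QD = QD, MQ = MQ, SOR = SOR,
    MQRankSum = MQRankSum, ReadPosRankSum = ReadPosRankSum,
    ad_ref = 15L, ad_alt = 15L, allele_fraction = allele_fraction, sex = sex
  )
}

# ---- independent NG86 oracle: recursive pathway enumeration ----------------

oracle_code <- as.list(Biostrings::GENETIC_CODE)

oracle_aa <- function(codon) oracle_code[[codon]]

# brute-force enumeration of all orderings of the differing positions by
# recursion (independent of the permutation-table implementation)
oracle_path_counts <- function(a, b) {
  if (a == b) return(c(sd = 0, nd = 0))
  recurse <- function(cur, target, respect_stops) {
    da <- strsplit(cur, "")[[1]]
    db <- strsplit(target, "")[[1]]
    dpos <- which(da != db)
    if (length(dpos) == 0L) {
      return(list(c(sd = 0, nd = 0)))
    }
    out <- list()
    for (p in dpos) {
      nxt <- da
      nxt[p] <- db[p]
      nxt_codon <- paste(nxt, collapse = "")
      if (respect_stops && oracle_aa(nxt_codon) == "*" && nxt_codon != target) next
      step <- if (oracle_aa(cur) == oracle_aa(nxt_codon)) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      for (tailcount in recurse(nxt_codon, target, respect_stops)) {
        out[[length(out) + 1L]] <- step + tailcount
      }
    }
    out
  }
  paths <- recurse(a, b, TRUE)
  if (length(paths) == 0L) paths <- recurse(a, b, FALSE)
  Reduce(`+`, paths) / length(paths)
}

oracle_site_fractions <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[p])) {
      mut <- bases
      mut[p] <- alt
      if (oracle_aa(paste(mut, collapse = "")) == oracle_aa(codon)) syn <- syn + 1 / 3
    }
  }
  c(S = syn, N = 3 - syn)
}

sense_codons <- function() {
  names(oracle_code)[unlist(oracle_code) != "*"]
}

# random non-overlapping left-normalized variant set for round trips;
# events spaced >= 12 bp apart
random_variant_set <- function(ref_seq, n_var) {
  len <- nchar(ref_seq)
  cand <- sort(sample(seq(10L, len - 10L), n_var))
  pos <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last >= 12L) {
      pos <- c(pos, p)
      last <- p
    }
  }
  rows <- lapply(pos, function(p) {
    kind <- sample(c("SNP", "INS", "DEL"), 1L)
    anchor <- substr(ref_seq, p, p)
    if (kind == "SNP") {
      tibble::tibble(pos = p, ref = anchor,
                     alt = sample(setdiff(c("A", "C", "G", "T"), anchor), 1L),
                     vtype = "SNP")
    } else if (kind == "INS") {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                   collapse = "")
      tibble::tibble(pos = p, ref = anchor, alt = paste0(anchor, ins), vtype = "INDEL")
    } else {
      k <- sample(1:3, 1)
      tibble::tibble(pos = p, ref = substr(ref_seq, p, p + k), alt = anchor,
                     vtype = "INDEL")
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- ztrscan:::left_normalize_variants(out, ref_seq)
  out <- dplyr::arrange(out, pos)
  # normalization can create overlaps/duplicates; drop them
  keep <- rep(TRUE, nrow(out))
  last_end <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$pos[i] <= last_end) keep[i] <- FALSE
    else last_end <- out$pos[i] + nchar(out$ref[i]) - 1L
  }
  out[keep, ]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
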