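# a clean single-exon gene: ATG + 8 sense codons + TAA at offset 10
toy_gene <- function(strand = "+") {
  mid <- "AAATTTGGGCCCAAATTTGGGCCC" # 8 sense codons
  orf <- paste0("ATG", mid, "TAA")
  if (strand == "-") orf <- ztrscan:::revcomp(orf)
  ref <- paste0(strrep("ACGT", 3), orf, strrep("TTCA", 10)) # 12 + 30 + 40 bp
  gene <- gene_models("g1", 10, 45, strand = strand,
                      cds = list(tibble::tibble(start = 12, end = 42)))
  list(ref = ref, gene = gene)
}

empty_vars <- tibble::tibble(pos = integer(), ref = character(),
                             alt = character(), vtype = character())
no_dels <- call_w_deletions(envelope = c(0, 82), candidates = list())

test_that("deletion containment drives deleted and partial calls", {
  genes <- gene_models(c("in", "straddle", "out"),
                       start = c(100, 180, 400), end = c(150, 250, 450))
  dels <- call_w_deletions(envelope = c(0, 1000),
                           candidates = list(c(50, 200)), min_run = 1L,
                           window_size = 50L)
  out <- intersect_gene_deletions(genes, dels)
  expect_equal(out$fate, c("deleted", "partial_deletion", "pending"))
  # a gene outside the envelope is skipped with a warning
  outside <- gene_models("far", 1500, 1600)
  expect_warning(res <- intersect_gene_deletions(outside, dels), "envelope")
  expect_equal(nrow(res), 0L)
})

test_that("an unchanged W copy is intact on both strands", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(strand)
    wp <- build_w_pseudosequence(tg$ref, c(0, 82), empty_vars)
    fate <- assess_orf(tg$gene[1, ], tg$ref, wp, no_dels)
    expect_equal(fate$fate, "intact")
    expect_true(is.na(fate$pseudogene_cause))
  }
})

test_that("a 1-bp deletion inside the CDS is a frameshift pseudogene", {
  tg <- toy_gene()
  # delete one base inside the CDS (anchor at pos 20, deletes pos 21)
  del <- tibble::tibble(pos = 20L, ref = substr(tg$ref, 20, 21),
                        alt = substr(tg$ref, 20, 20), vtype = "INDEL")
  wp <- build_w_pseudosequence(tg$ref, c(0, 82), del)
  fate <- assess_orf(tg$gene[1, ], tg$ref, wp, no_dels)
  expect_equal(fate$fate, "pseudogene")
  expect_equal(fate$pseudogene_cause, "frameshift")
})

test_that("a nonsense substitution is a premature-stop pseudogene", {
  tg <- toy_gene()
  # CDS starts at 12 (0-based): codon 2 occupies positions 16-18 (1-based),
  # reference AAA; change to TAA
  stopifnot(substr(tg$ref, 16, 18) == "AAA")
  snp <- tibble::tibble(pos = 16L, ref = "A", alt = "T", vtype = "SNP")
  wp <- build_w_pseudosequence(tg$ref, c(0, 82), snp)
  fate <- assess_orf(tg$gene[1, ], tg$ref, wp, no_dels)
  expect_equal(fate$fate, "pseudogene")
  expect_equal(fate$pseudogene_cause, "premature_stop")
})

test_that("synonymous substitutions leave the gene intact", {
  tg <- toy_gene()
  # codon 2 AAA (Lys) -> AAG (Lys): third position at 1-based 18
  snp <- tibble::tibble(pos = 18L, ref = "A", alt = "G", vtype = "SNP")
  wp <- build_w_pseudosequence(tg$ref, c(0, 82), snp)
  fate <- assess_orf(tg$gene[1, ], tg$ref, wp, no_dels)
  expect_equal(fate$fate, "intact")
})

test_that("frameshift and downstream stop together are cause 'both'", {
  tg <- toy_gene()
  vars <- tibble::tibble(
    pos = c(16L, 20L),
    ref = c("A", substr(tg$ref, 20, 21)),
    alt = c("T", substr(tg$ref, 20, 20)),
    vtype = c("SNP", "INDEL")
  )
  wp <- build_w_pseudosequence(tg$ref, c(0, 82), vars)
  fate <- assess_orf(tg$gene[1, ], tg$ref, wp, no_dels)
  expect_equal(fate$pseudogene_cause, "both")
})

test_that("fate summaries reproduce the survival arithmetic", {
  bop9 <- tibble::tibble(
    name = paste0("g", 1:9),
    fate = c(rep("intact", 2), rep("deleted", 5), rep("partial_deletion", 2))
  )
  s <- summarize_fates(bop9)
  expect_equal(s$percent_lost, 78)
  expect_equal(s$survival_fraction, 2 / 9)

  all_ok <- tibble::tibble(name = c("a", "b"), fate = c("intact", "intact"))
  expect_equal(summarize_fates(all_ok)$survival_fraction, 1)

  pooled <- summarize_fates(list(
    bop = tibble::tibble(fate = c(rep("intact", 2), rep("deleted", 4),
                                  rep("partial_deletion", 2))),
    finch = tibble::tibble(fate = c(rep("intact", 4), "pseudogene")),
    tit = tibble::tibble(fate = "intact")
  ))
  pooled_row <- pooled[pooled$lineage == "pooled", ]
  expect_equal(pooled_row$n_genes, 14)
  expect_equal(pooled_row$n_functional, 7)
  # categories are exhaustive: counts sum to the gene total
  expect_equal(
    pooled_row$intact + pooled_row$deleted + pooled_row$partial_deletion +
      pooled_row$pseudogene,
    pooled_row$n_genes
  )
})
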