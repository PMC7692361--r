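test_that("substitutions and insertions are applied with exact length bookkeeping", {
  snp <- tibble::tibble(pos = 2L, ref = "C", alt = "T", vtype = "SNP")
  wp <- build_w_pseudosequence("ACGT", c(0, 4), snp)
  expect_equal(wp$sequence, "ATGT")

  ins <- tibble::tibble(pos = 2L, ref = "C", alt = "CAA", vtype = "INDEL")
  wp2 <- build_w_pseudosequence("ACGT", c(0, 4), ins)
  expect_equal(wp2$sequence, "ACAAGT")
  expect_equal(nchar(wp2$sequence), 4 + 2)
  expect_equal(wp2$coord_map$cumulative_offset, 2L)

  del <- tibble::tibble(pos = 1L, ref = "AC", alt = "A", vtype = "INDEL")
  wp3 <- build_w_pseudosequence("ACGT", c(0, 4), del)
  expect_equal(wp3$sequence, "AGT")
})

test_that("reference mismatches error with position; overlapping variants are skipped", {
  bad <- tibble::tibble(pos = 2L, ref = "G", alt = "T", vtype = "SNP")
  expect_error(build_w_pseudosequence("ACGT", c(0, 4), bad), "position 2")

  ovl <- tibble::tibble(
    pos = c(2L, 3L), ref = c("CG", "G"), alt = c("C", "A"), vtype = "INDEL"
  )
  wp <- build_w_pseudosequence("ACGT", c(0, 4), ovl)
  expect_equal(nrow(wp$applied_variants), 1L) # leftmost wins
  expect_equal(nrow(wp$skipped_variants), 1L)
  expect_equal(wp$sequence, "ACT")
})

test_that("liftover is the identity without indels and shifts by indel offsets", {
  ref <- strrep("ACGT", 25) # 100 bp
  wp0 <- build_w_pseudosequence(ref, c(0, 100),
                                tibble::tibble(pos = integer(), ref = character(),
                                               alt = character(), vtype = character()))
  lift <- liftover(wp0, c(10, 20))
  expect_equal(lift$status, "mapped")
  expect_equal(c(lift$w_start, lift$w_end), c(10, 20))

  ins <- tibble::tibble(pos = 5L, ref = "A", alt = "ATT", vtype = "INDEL")
  wp1 <- build_w_pseudosequence(ref, c(0, 100), ins)
  lift1 <- liftover(wp1, c(10, 20))
  expect_equal(c(lift1$w_start, lift1$w_end), c(12, 22))

  dels <- tibble::tibble(start = 40, end = 60)
  expect_equal(liftover(wp0, c(45, 55), deletions = dels)$status, "deleted")
  part <- liftover(wp0, c(35, 55), deletions = dels)
  expect_equal(part$status, "partial")
  expect_equal(c(part$w_start, part$w_end), c(35, 40))
  expect_error(liftover(wp0, c(90, 120)), "envelope")
})

test_that("round-trip variant recovery is exact for random non-overlapping sets", {
  set.seed(101)
  for (rep in 1:20) {
    ref <- random_seq(2000)
    vars <- random_variant_set(ref, 40)
    wp <- build_w_pseudosequence(ref, c(0, 2000), vars)
    # exact length bookkeeping
    expect_equal(nchar(wp$sequence),
                 2000 + sum(nchar(wp$applied_variants$alt) -
                              nchar(wp$applied_variants$ref)))
    rec <- rederive_variants(ref, wp$sequence)
    expect_equal(rec$pos, wp$applied_variants$pos)
    expect_equal(rec$ref, wp$applied_variants$ref)
    expect_equal(rec$alt, wp$applied_variants$alt)
  }
})

test_that("forward mapping is consistent with sequence content at unaffected positions", {
  set.seed(77)
  ref <- random_seq(1000)
  vars <- random_variant_set(ref, 25)
  wp <- build_w_pseudosequence(ref, c(0, 1000), vars)
  indel_spans <- wp$applied_variants[wp$applied_variants$vtype == "INDEL", ]
  probe <- setdiff(seq(0, 995, by = 7), unlist(lapply(seq_len(nrow(indel_spans)),
    function(i) seq(indel_spans$pos[i] - 1, indel_spans$pos[i] + nchar(indel_spans$ref[i])))))
  snp_pos <- wp$applied_variants$pos[wp$applied_variants$vtype == "SNP"] - 1L
  probe <- setdiff(probe, snp_pos)
  for (p in probe) {
    w <- ztrscan:::z_to_w_pos(wp, p)
    expect_equal(substr(wp$sequence, w + 1, w + 1), substr(ref, p + 1, p + 1))
  }
})

test_that("deletion accounting is exact and reports the retained length", {
  dels <- call_w_deletions(envelope = c(0, 1.3e6),
                           candidates = list(c(3e5, 3e5 + 583e3)))
  g <- glance(dels)
  expect_equal(g$total_deleted, 583e3)
  expect_equal(g$retained_length, 1.3e6 - 583e3)
  expect_equal(g$retained_mb, 0.7)
  expect_equal(g$retained_length + g$total_deleted, 1.3e6)

  # no candidates: retained = envelope
  none <- call_w_deletions(envelope = c(0, 5e5))
  expect_equal(glance(none)$retained_length, 5e5)
  # sub-min_run candidates are dropped
  short <- call_w_deletions(envelope = c(0, 5e5), candidates = list(c(0, 50000)),
                            min_run = 2L)
  expect_equal(nrow(short), 0L)
})
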