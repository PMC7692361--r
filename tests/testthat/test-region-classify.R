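# build a combined window table with exact expectation values
expected_windows <- function(labels, lambda_bg = 5, d_density = 100,
                             psv_density = 50, wsize = 50000L) {
  n <- length(labels)
  f_cov <- c(ZTR = 1, PAR = 1, Z_DUP = 1, HEMIZYGOUS_Z = 0.5)[labels]
  m_cov <- c(ZTR = 1, PAR = 1, Z_DUP = 2, HEMIZYGOUS_Z = 1)[labels]
  f_den <- c(ZTR = d_density, PAR = lambda_bg, Z_DUP = psv_density,
             HEMIZYGOUS_Z = lambda_bg)[labels]
  m_den <- c(ZTR = lambda_bg, PAR = lambda_bg, Z_DUP = psv_density,
             HEMIZYGOUS_Z = lambda_bg)[labels]
  tibble::tibble(
    chrom = "chr1", start = (seq_len(n) - 1L) * wsize, end = seq_len(n) * wsize,
    excluded = FALSE,
    norm_cov_f = unname(f_cov), norm_cov_m = unname(m_cov),
    snp_density_f = unname(f_den), snp_density_m = unname(m_den)
  )
}

test_that("noise-free signatures classify exactly to the planted labels", {
  truth <- c(rep("PAR", 4), rep("HEMIZYGOUS_Z", 6), rep("ZTR", 5),
             rep("HEMIZYGOUS_Z", 3), rep("Z_DUP", 2), rep("HEMIZYGOUS_Z", 4))
  w <- expected_windows(truth)
  base <- tibble::tibble(chrom = "chr1", start = 0, end = 4 * 50000)
  out <- classify_windows(w, baseline = base)
  expect_equal(out$label, truth)
  lam <- attr(out, "lambda_bg")
  expect_equal(lam$female, 5)
  expect_equal(lam$threshold_female, max(15, 5 + 3 * sqrt(5)))
})

test_that("single-window signatures match the documented cases", {
  w <- expected_windows(rep("PAR", 12))
  # overwrite three windows with the canonical signatures
  w$snp_density_f[5] <- 100 # ZTR: female-only elevation at diploid coverage
  w$norm_cov_f[6] <- 0.5 # hemizygous female
  w$norm_cov_m[7] <- 2
  w$snp_density_f[7] <- 50
  w$snp_density_m[7] <- 50 # duplication: both sexes elevated + male coverage
  base <- tibble::tibble(chrom = "chr1", start = 0, end = 4 * 50000)
  out <- classify_windows(w, baseline = base)
  expect_equal(out$label[5], "ZTR")
  expect_equal(out$label[6], "HEMIZYGOUS_Z")
  expect_equal(out$label[7], "Z_DUP")
  expect_equal(out$label[1], "PAR")
})

test_that("merging respects min_run, bridges noise windows and builds ZTR envelopes", {
  base <- tibble::tibble(chrom = "chr1", start = 0, end = 2 * 50000)

  # [H,H,Z,Z,Z,H] -> one 3-window ZTR call
  w1 <- expected_windows(c("HEMIZYGOUS_Z", "HEMIZYGOUS_Z", "ZTR", "ZTR", "ZTR",
                           "HEMIZYGOUS_Z"))
  w1$label <- c("HEMIZYGOUS_Z", "HEMIZYGOUS_Z", "ZTR", "ZTR", "ZTR", "HEMIZYGOUS_Z")
  r1 <- merge_calls(w1)
  ztr1 <- r1[r1$label == "ZTR", ]
  expect_equal(nrow(ztr1), 1L)
  expect_equal(ztr1$n_windows, 3L)

  # an isolated ZTR window is demoted
  w2 <- w1
  w2$label <- c("HEMIZYGOUS_Z", "HEMIZYGOUS_Z", "ZTR", "HEMIZYGOUS_Z",
                "HEMIZYGOUS_Z", "HEMIZYGOUS_Z")
  r2 <- merge_calls(w2)
  expect_false(any(r2$label == "ZTR"))

  # [Z,Z,H,H,H,Z,Z] -> 7-window envelope with one interior deletion candidate
  w3 <- expected_windows(rep("ZTR", 7))
  w3$label <- c("ZTR", "ZTR", "HEMIZYGOUS_Z", "HEMIZYGOUS_Z", "HEMIZYGOUS_Z",
                "ZTR", "ZTR")
  r3 <- merge_calls(w3)
  ztr3 <- r3[r3$label == "ZTR", ]
  expect_equal(ztr3$n_windows, 7L)
  cand <- ztr3$w_deletion_candidates[[1]]
  expect_equal(length(cand), 1L)
  expect_equal(cand[[1]], c(2 * 50000, 5 * 50000))

  # a single interior excluded window is bridged
  w4 <- expected_windows(rep("ZTR", 5))
  w4$label <- c("ZTR", "ZTR", "EXCLUDED", "ZTR", "ZTR")
  w4$excluded[3] <- TRUE
  r4 <- merge_calls(w4)
  expect_equal(r4$n_windows[r4$label == "ZTR"], 5L)
})

test_that("region evidence carries one-sided rank-sum p-values against the baseline", {
  truth <- c(rep("PAR", 10), rep("ZTR", 6))
  w <- expected_windows(truth)
  w$label <- truth
  base <- tibble::tibble(chrom = "chr1", start = 0, end = 10 * 50000)
  r <- merge_calls(w, baseline = base)
  ztr <- r[r$label == "ZTR", ]
  # fully separated samples: p = 1 / choose(16, 6)
  expect_equal(ztr$p_density_f, 1 / choose(16, 6))
  expect_true(is.na(r$p_density_f[r$label == "PAR"]))
})
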