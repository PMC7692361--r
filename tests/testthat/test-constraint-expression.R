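test_that("haploinsufficiency percentiles count background scores at or below the query", {
  tab <- tibble::tibble(gene = c("a", "b", "c", "d", "q"),
                        score = c(0.1, 0.2, 0.3, 0.4, 0.3))
  res <- hi_percentile(tab, background_genes = c("a", "b", "c", "d"),
                       query_genes = "q")
  expect_equal(res$percentiles$percentile, 75)
  # a query equal to the background maximum sits at the 100th percentile
  res2 <- hi_percentile(tab, c("a", "b", "c", "d"), "d")
  expect_equal(res2$percentiles$percentile, 100)
  # ECDF spans (0, 1]
  expect_equal(max(res$ecdf$cumulative_fraction), 1)
  expect_true(min(res$ecdf$cumulative_fraction) > 0)
})

test_that("percentiles match a naive counting oracle and are monotone in score", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    tab <- tibble::tibble(gene = paste0("g", 1:n), score = round(runif(n), 2))
    bg <- tab$gene
    qs <- sample(tab$gene, 5)
    res <- hi_percentile(tab, bg, qs)$percentiles
    naive <- vapply(qs, function(q) {
      s <- tab$score[tab$gene == q]
      100 * sum(tab$score <= s) / n
    }, numeric(1))
    expect_equal(res$percentile, unname(naive))
    ord <- order(res$score)
    expect_true(all(diff(res$percentile[ord]) >= 0))
  }
})

test_that("invalid or missing haploinsufficiency input is reported", {
  tab <- tibble::tibble(gene = "a", score = 0.5)
  expect_error(hi_percentile(tibble::tibble(gene = "a", score = 1.2), "a", "a"),
               "\\[0, 1\\]")
  expect_error(hi_percentile(tab, character(0), "a"), "background")
  expect_warning(res <- hi_percentile(tab, "a", c("a", "zz")), "missing")
  expect_true(is.na(res$percentiles$percentile[2]))
})

test_that("expression means are replicate-averaged and log1p uses natural log", {
  tpm <- tibble::tibble(
    species = "sp", tissue = "gonad", sex = "female",
    replicate = c(1, 2), gene = "g", tpm = c(2, 4)
  )
  prof <- suppressWarnings(expression_profile(tpm))
  expect_equal(prof$profile$mean_tpm, 3)
  expect_equal(prof$profile$log1p_tpm, log(4))
})

test_that("gonad bias flags follow the fold threshold and skip absent conditions", {
  base <- tidyr::expand_grid(
    species = "sp", tissue = c("gonad", "brain", "liver"),
    sex = c("female", "male"), replicate = 1:2, gene = c("bias", "flat")
  )
  base$tpm <- 5
  base$tpm[base$gene == "bias" & base$tissue == "gonad" & base$sex == "female"] <- 50
  prof <- expression_profile(base, bias_fold_threshold = 2)
  expect_true(prof$bias$gonad_biased[prof$bias$gene == "bias"])
  expect_false(prof$bias$gonad_biased[prof$bias$gene == "flat"])

  # a condition absent for one gene is a blank cell, not a zero
  drop_one <- base[!(base$gene == "flat" & base$tissue == "liver"), ]
  prof2 <- expression_profile(drop_one)
  cells <- prof2$profile[prof2$profile$gene == "flat", ]
  expect_false(any(cells$tissue == "liver"))

  expect_error(expression_profile(dplyr::mutate(base, tpm = -1)), "negative")
})
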