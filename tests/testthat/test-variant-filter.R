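test_that("each hard-filter criterion fails at its stated threshold", {
  cases <- list(
    list(args = list(pos = 100, QD = 1.5), reason = "QD"),
    list(args = list(pos = 200, FS = 10.5), reason = "FS"),
    list(args = list(pos = 300, MQ = 49), reason = "MQ"),
    list(args = list(pos = 400, SOR = 1.6), reason = "SOR"),
    list(args = list(pos = 500, MQRankSum = -2), reason = "MQRankSum"),
    list(args = list(pos = 600, ReadPosRankSum = -9), reason = "ReadPosRankSum")
  )
  rec <- dplyr::bind_rows(lapply(cases, function(cc) do.call(make_record, cc$args)))
  out <- hard_filter(rec)
  expect_equal(out$filter, vapply(cases, `[[`, character(1), "reason"))
  expect_false(any(out$pass))
  # a clean isolated record passes
  expect_true(hard_filter(make_record(1000))$pass)
  # boundary values are not violations (rules are strict inequalities)
  edge <- hard_filter(make_record(50, FS = 10, QD = 2, MQ = 50, SOR = 1.5,
                                  MQRankSum = -1.5, ReadPosRankSum = -8))
  expect_true(edge$pass)
})

test_that("multiple violations are all recorded", {
  rec <- make_record(100, FS = 20, QD = 1)
  out <- hard_filter(rec)
  expect_setequal(strsplit(out$filter, ";")[[1]], c("FS", "QD"))
})

test_that("the 10-bp SNP cluster rule fails both members and spares indels", {
  rec <- dplyr::bind_rows(
    make_record(100), make_record(105),
    make_record(300), # isolated
    make_record(400), make_record(403, ref = "A", alt = "AT", vtype = "INDEL")
  )
  out <- hard_filter(rec)
  expect_equal(out$filter[1:2], c("cluster", "cluster"))
  expect_true(out$pass[3])
  expect_true(out$pass[4]) # neighbouring indel does not form a SNP cluster
  expect_true(out$pass[5]) # indels exempt from the cluster rule
  # two SNPs 10 bp apart do not fit inside one 10-bp span
  far <- hard_filter(dplyr::bind_rows(make_record(100), make_record(110)))
  expect_true(all(far$pass))
})

test_that("missing annotations leave a criterion unapplied and input order is enforced", {
  rec <- make_record(100, QD = NA)
  expect_true(hard_filter(rec)$pass)
  unsorted <- dplyr::bind_rows(make_record(200), make_record(100))
  expect_error(hard_filter(unsorted), "sorted")
})

test_that("allele-fraction window is closed at 0.3 and 0.7", {
  rec <- hard_filter(dplyr::bind_rows(
    make_record(100, allele_fraction = 0.5),
    make_record(200, allele_fraction = 0.75),
    make_record(300, allele_fraction = 0.3),
    make_record(400, allele_fraction = 0.7),
    make_record(500, allele_fraction = 0.29),
    make_record(600, allele_fraction = NA)
  ))
  expect_warning(out <- allele_fraction_filter(rec), "missing allele fraction")
  expect_equal(out$pos, c(100L, 300L, 400L))
  expect_equal(attr(out, "n_missing_af"), 1L)
  expect_equal(attr(out, "n_af_dropped"), 2L)
})

test_that("filtering partitions the input and SNP density counts are conserved", {
  set.seed(9)
  pos <- sort(sample(1:200000, 400))
  rec <- dplyr::bind_rows(lapply(pos, function(p) make_record(p)))
  rec$QD[sample(400, 50)] <- 1 # plant failures
  out <- hard_filter(rec)
  expect_equal(sum(out$pass) + sum(!out$pass), nrow(rec))

  kept <- suppressWarnings(allele_fraction_filter(out))
  win <- window_coverage(
    tibble::tibble(chrom = "chr1", pos = 1:200000, depth = 10),
    chrom_length = 200000
  )
  dens <- snp_density(kept, win, "female")
  expect_equal(sum(dens$snp_count_f), nrow(kept))
  # empty record set gives all-zero densities
  empty <- snp_density(kept[0, ], win, "male")
  expect_true(all(empty$snp_count_m == 0))
})

test_that("density assigns 1-based positions to 0-based half-open windows", {
  win <- window_coverage(
    tibble::tibble(chrom = "chr1", pos = 1:100000, depth = 10),
    chrom_length = 100000
  )
  # pos 50000 is the last site of window [0, 50000); pos 50011 in the next
  # window (spaced beyond the cluster span)
  rec <- hard_filter(dplyr::bind_rows(make_record(50000), make_record(50011)))
  kept <- allele_fraction_filter(rec)
  dens <- snp_density(kept, win, "female")
  expect_equal(dens$snp_count_f, c(1L, 1L))
})
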