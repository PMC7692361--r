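test_that("layout validation rejects malformed region tilings", {
  expect_error(
    sim_layout("c", 100, regions = tibble::tibble(
      start = c(0, 40), end = c(50, 100), class = c("PAR", "ZTR")
    )),
    "tile"
  )
  expect_error(
    sim_layout("c", 100, regions = tibble::tibble(
      start = 0, end = 100, class = "PAR"
    ), w_deletions = tibble::tibble(start = 10, end = 20)),
    "exactly one ZTR"
  )
})

test_that("the same seed reproduces every emitter byte for byte", {
  lay <- small_layout()
  s1 <- simulate_reference(lay, sim_params(seed = 5))
  s2 <- simulate_reference(lay, sim_params(seed = 5))
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$truth$shared_variants, s2$truth$shared_variants)
  expect_identical(simulate_depth(s1, "female"), simulate_depth(s2, "female"))
  expect_identical(simulate_variants(s1, "male"), simulate_variants(s2, "male"))
  s3 <- simulate_reference(lay, sim_params(seed = 6))
  expect_false(identical(s1$reference, s3$reference))
  # call order does not matter
  expect_identical(simulate_variants(s1, "female"), simulate_variants(s2, "female"))
})

test_that("truth carries one label per full window (10 Mb / 50 kb = 200)", {
  sim <- simulate_reference(default_sim_layout(), sim_params(seed = 1))
  expect_equal(nrow(sim$truth$window_labels), 200L)
  # W-deletion windows carry the hemizygous signature label
  del_win <- sim$truth$window_labels$start >= 6.0e6 &
    sim$truth$window_labels$end <= 6.15e6
  expect_true(all(sim$truth$window_labels$label[del_win] == "HEMIZYGOUS_Z"))
  # genes wholly inside the planted deletion are deleted in truth
  tf <- sim$truth$gene_fates
  expect_equal(tf$fate[tf$name == "ZFAND5"], "deleted")
  expect_equal(tf$fate[tf$name == "TMC1"], "partial_deletion")
})

test_that("depth means converge to copy number times haploid depth", {
  lay <- small_layout()
  sim <- simulate_reference(lay, sim_params(seed = 2))
  D <- sim$params$haploid_depth

  check_region <- function(depth, start, end, c_expected) {
    d <- depth$depth[depth$pos > start & depth$pos <= end]
    se <- sqrt(c_expected * D / length(d))
    expect_lt(abs(mean(d) - c_expected * D), 3 * se)
  }
  fem <- simulate_depth(sim, "female")
  male <- simulate_depth(sim, "male")
  check_region(fem, 2e5, 8e5, 1) # hemizygous female
  check_region(fem, 0, 2e5, 2) # PAR
  check_region(male, 1.7e6, 1.8e6, 4) # male duplication
  check_region(fem, 1.0e6, 1.15e6, 1) # female W-deletion inside ZTR
  # ZTR outside the deletion: female ~ male
  f_ztr <- mean(fem$depth[fem$pos > 8e5 & fem$pos <= 1e6])
  m_ztr <- mean(male$depth[male$pos > 8e5 & male$pos <= 1e6])
  expect_lt(abs(f_ztr - m_ztr), 4 * sqrt(2 * 2 * D / 2e5))
  expect_error(simulate_depth(sim, "unknown"), "sex")
})

test_that("variant emission matches the planted rates and sexes", {
  lay <- small_layout()
  prm <- sim_params(seed = 3)
  sim <- simulate_reference(lay, prm)
  fem <- simulate_variants(sim, "female")
  male <- simulate_variants(sim, "male")

  # male records in the ZTR are background-only
  ztr_len <- 6e5
  m_ztr <- sum(male$pos > 8e5 & male$pos <= 1.4e6)
  lam <- prm$background_het * ztr_len
  expect_lt(abs(m_ztr - lam), max(4 * sqrt(lam), 10))
  f_ztr <- sum(fem$pos > 8e5 & fem$pos <= 1.4e6)
  expect_gt(f_ztr, 5 * m_ztr)

  # female-minus-male count difference tracks the divergence rate
  d_len <- prm$zw_divergence * (6e5 - 1.5e5)
  expect_lt(abs((f_ztr - m_ztr) - d_len), 4 * sqrt(d_len))

  # PSVs are shared between the sexes at identical positions
  psv_f <- fem$pos[fem$provenance == "psv"]
  psv_m <- male$pos[male$provenance == "psv"]
  expect_identical(psv_f, psv_m)

  # records are sorted and unique per position
  expect_false(is.unsorted(fem$pos))
  expect_equal(anyDuplicated(fem$pos), 0L)
})

test_that("planted hard-filter failures appear at the configured fraction", {
  lay <- small_layout()
  sim0 <- simulate_reference(lay, sim_params(seed = 4, fail_fraction = 0))
  fem0 <- simulate_variants(sim0, "female")
  filt0 <- hard_filter(fem0)
  # with no planted failures, only the cluster rule can fire
  reasons <- unlist(strsplit(filt0$filter[!filt0$pass], ";"))
  expect_true(all(reasons == "cluster"))

  sim <- simulate_reference(lay, sim_params(seed = 4, fail_fraction = 0.1))
  fem <- simulate_variants(sim, "female")
  filt <- hard_filter(fem)
  planted <- !is.na(fem$planted_fail)
  # every planted record fails with (at least) its planted reason
  expect_true(all(!filt$pass[planted]))
  expect_true(all(mapply(function(f, r) r %in% strsplit(f, ";")[[1]],
                         filt$filter[planted], fem$planted_fail[planted])))
  # fraction close to the configured value (binomial error)
  n <- nrow(fem)
  expect_lt(abs(mean(planted) - 0.1), 4 * sqrt(0.1 * 0.9 / n))
})

test_that("codon alignments honour branch length and omega constraints", {
  aln <- simulate_codon_alignment(
    200,
    branches = tibble::tibble(name = c("outgroup", "Z", "W"),
                              length = c(0.1, 0, 0.04),
                              omega = c(0.5, 0.5, 0)),
    seed = 9
  )
  # zero-length branch: child identical to the ancestor
  expect_identical(aln$sequences[["Z"]], aln$ancestor)
  # omega 0: no nonsynonymous substitutions realized
  expect_equal(aln$truth$nd_true[aln$truth$name == "W"], 0L)
  # alignments are gap-free, in frame, and stop-free
  for (sq in aln$sequences) {
    expect_equal(nchar(sq) %% 3, 0)
    aa <- ztrscan:::translate_codons(ztrscan:::split_codons(sq))
    expect_false(any(aa == "*"))
  }
  expect_warning(simulate_codon_alignment(20, seed = 1), "50 codons")
})

test_that("expression tables have the declared design and plant the bias", {
  tpm <- simulate_expression(c("gA", "gB"), biased_genes = "gA", seed = 2)
  counts <- dplyr::count(tpm, gene, species, tissue, sex)
  expect_true(all(counts$n == 2)) # two replicates per condition
  prof <- expression_profile(tpm)
  expect_true(prof$bias$gonad_biased[prof$bias$gene == "gA"])
  expect_false(prof$bias$gonad_biased[prof$bias$gene == "gB"])
  expect_error(simulate_expression("g", tissues = c("brain")), "gonad")
})

test_that("simulation artefacts round-trip through their interchange formats", {
  lay <- small_layout()
  sim <- simulate_reference(lay, sim_params(seed = 7))
  tmp <- withr::local_tempdir()

  fem <- simulate_variants(sim, "female")
  vcf <- file.path(tmp, "f.vcf")
  write_vcf(fem, vcf)
  back <- read_vcf(vcf, sex = "female")
  expect_equal(back$pos, fem$pos)
  expect_equal(back$ref, fem$ref)
  expect_equal(back$alt, fem$alt)
  expect_equal(back$QD, fem$QD, tolerance = 1e-3)
  expect_equal(back$allele_fraction, fem$allele_fraction, tolerance = 1e-9)

  dep <- simulate_depth(sim, "male")
  dpath <- file.path(tmp, "m.tsv")
  write_depth(dep, dpath)
  expect_equal(read_depth(dpath), dep)

  fa <- file.path(tmp, "ref.fa")
  write_fasta(c(chrZ_t = sim$reference), fa)
  expect_equal(unname(read_fasta(fa)[1]), sim$reference)

  gff <- file.path(tmp, "genes.gff3")
  write_gene_models(lay$genes, gff, "chrZ_t")
  back_genes <- read_gene_models(gff)
  expect_equal(back_genes$name, lay$genes$name)
  expect_equal(back_genes$start, lay$genes$start)
  expect_equal(back_genes$end, lay$genes$end)
  expect_equal(back_genes$cds[[1]]$start, lay$genes$cds[[1]]$start)

  write_sim(sim, file.path(tmp, "simdir"))
  truth <- yaml::read_yaml(file.path(tmp, "simdir", "truth.yaml"))
  expect_equal(length(truth$window_labels), 40L)
  expect_equal(truth$gene_fates$geneC, "deleted")
})
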