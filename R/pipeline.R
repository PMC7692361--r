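# End-to-end orchestration: simulate (or read) -> windows -> filter ->
# classify -> reconstruct -> gene fates, with a reproducible summary.

#' Build a pipeline configuration
#'
#' Either a simulation block (layout + parameters) or paths/tables for real
#' inputs. All filter thresholds default to the standard hard-filter
#' values; any override is echoed in the run summary.
#'
#' @param simulate `TRUE` to run on synthetic data (default), or `FALSE`
#'   with explicit inputs.
#' @param layout a [sim_layout()]; default [default_sim_layout()].
#' @param params a [sim_params()].
#' @param inputs for `simulate = FALSE`: a list with `reference` (FASTA
#'   path or string), `depth_female`, `depth_male` (paths or tibbles),
#'   `vcf_female`, `vcf_male` (paths or tibbles), `genes` (GFF3 path or
#'   gene model tibble), `chrom_length`.
#' @param window_size analysis window in bp; default 50,000.
#' @param baseline declared baseline (autosome-like or PAR) intervals used
#'   for coverage normalization and background SNP density, as a tibble
#'   `chrom`, `start`, `end`; `"layout"` (default) uses the declared
#'   AUTOSOME_LIKE regions of the simulated layout, falling back to its
#'   PAR regions.
#' @param classify a [classify_params()].
#' @param af_bounds allele-fraction retention bounds; default
#'   `c(0.3, 0.7)`.
#' @param outdir optional output directory for stage artefacts.
#' @param seed seed overriding `params$seed` when simulating.
#' @return A `ztr_run_config` list.
#' @export
run_config <- function(simulate = TRUE, layout = default_sim_layout(),
                       params = sim_params(), inputs = NULL,
                       window_size = 50000L, baseline = "layout",
                       classify = classify_params(), af_bounds = c(0.3, 0.7),
                       outdir = NULL, seed = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  structure(
    list(simulate = simulate, layout = layout, params = params,
         inputs = inputs, window_size = as.integer(window_size),
         baseline = baseline, classify = classify, af_bounds = af_bounds,
         outdir = outdir),
    class = "ztr_run_config"
  )
}

#' Run the full ZTR detection pipeline
#'
#' Stages: per-sex site filtering and window coverage, normalization
#' against the declared baseline, variant hard filtering and
#' allele-fraction retention, per-sex SNP density, window classification,
#' region-call merging with rank-sum evidence, W pseudo-sequence
#' reconstruction per ZTR call, W-deletion calling, and gene-fate
#' classification. Deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @return A `ztr_run` list: `windows` (labelled combined window table),
#'   `regions`, `ztr` (per-ZTR list of `wpseq`, `deletions`, `fates`),
#'   `fate_summary`, `config`, and when simulating, `sim` (with truth).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "ztr_run_config")) rlang::abort("config must come from run_config()")
  sim <- NULL
  if (isTRUE(config$simulate)) {
    sim <- simulate_reference(config$layout, config$params)
    reference <- sim$reference
    genes <- config$layout$genes
    chrom_length <- config$layout$chrom_length
    depth <- list(female = simulate_depth(sim, "female"),
                  male = simulate_depth(sim, "male"))
    variants <- list(female = simulate_variants(sim, "female"),
                     male = simulate_variants(sim, "male"))
  } else {
    inp <- config$inputs
    needed <- c("reference", "depth_female", "depth_male", "vcf_female", "vcf_male")
    missing <- needed[!needed %in% names(inp)]
    if (length(missing) > 0L) {
      rlang::abort(paste0("missing pipeline inputs: ", paste(missing, collapse = ", ")))
    }
    reference <- if (file.exists(inp$reference[1])) read_fasta(inp$reference)[[1]] else inp$reference
    load_tbl <- function(x, reader) if (is.character(x)) reader(x) else tibble::as_tibble(x)
    depth <- list(female = load_tbl(inp$depth_female, read_depth),
                  male = load_tbl(inp$depth_male, read_depth))
    variants <- list(
      female = if (is.character(inp$vcf_female)) read_vcf(inp$vcf_female, "female") else tibble::as_tibble(inp$vcf_female),
      male = if (is.character(inp$vcf_male)) read_vcf(inp$vcf_male, "male") else tibble::as_tibble(inp$vcf_male)
    )
    genes <- if (is.null(inp$genes)) gene_models(character(), numeric(), numeric())
      else if (is.character(inp$genes)) read_gene_models(inp$genes)
      else tibble::as_tibble(inp$genes)
    chrom_length <- inp$chrom_length %||% nchar(reference)
  }

  baseline <- resolve_baseline(config, sim)

  per_sex <- lapply(c(female = "female", male = "male"), function(sx) {
    sites <- site_filter(depth[[sx]])
    win <- window_coverage(sites, chrom_length = chrom_length,
                           window_size = config$window_size)
    win <- normalize_coverage(win, baseline = baseline,
                              baseline_kind = attr(baseline, "kind"))
    filt <- hard_filter(variants[[sx]])
    kept <- allele_fraction_filter(filt, config$af_bounds[1], config$af_bounds[2])
    win <- snp_density(kept, win, sx)
    list(windows = win, filtered = filt, retained = kept)
  })

  combined <- combine_sexes(per_sex$female$windows, per_sex$male$windows)
  labelled <- classify_windows(combined, params = config$classify,
                               baseline = baseline)
  regions <- merge_calls(labelled, params = config$classify, baseline = baseline)

  ztr_calls <- regions[regions$label == "ZTR", ]
  ztr_results <- lapply(seq_len(nrow(ztr_calls)), function(i) {
    call <- ztr_calls[i, ]
    dels <- call_w_deletions(call, min_run = config$classify$min_run,
                             window_size = config$window_size)
    fem <- per_sex$female$retained
    inside <- fem$pos > call$start & (fem$pos + nchar(fem$ref) - 1L) <= call$end
    wp <- build_w_pseudosequence(reference, c(call$start, call$end), fem[inside, ])
    g_in <- genes[genes$start >= call$start & genes$end <= call$end, , drop = FALSE]
    fates <- if (nrow(g_in) > 0L) gene_fates(g_in, reference, wp, dels) else NULL
    list(call = call, deletions = dels, wpseq = wp, fates = fates)
  })
  all_fates <- dplyr::bind_rows(purrr::compact(purrr::map(ztr_results, "fates")))
  fate_summary <- if (nrow(all_fates) > 0L) summarize_fates(all_fates) else NULL

  run <- structure(
    list(windows = labelled, regions = regions, ztr = ztr_results,
         fates = all_fates, fate_summary = fate_summary,
         per_sex = per_sex, config = config, sim = sim),
    class = "ztr_run"
  )
  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

resolve_baseline <- function(config, sim) {
  b <- config$baseline
  if (is.data.frame(b)) {
    attr(b, "kind") <- "declared"
    return(b)
  }
  if (identical(b, "layout") && !is.null(config$layout)) {
    rg <- config$layout$regions
    chrom <- config$layout$chrom_name
    auto <- rg[rg$class == "AUTOSOME_LIKE", ]
    if (nrow(auto) > 0L) {
      out <- tibble::tibble(chrom = chrom, start = auto$start, end = auto$end)
      attr(out, "kind") <- "autosome"
      return(out)
    }
    par <- rg[rg$class == "PAR", ]
    if (nrow(par) > 0L) {
      out <- tibble::tibble(chrom = chrom, start = par$start, end = par$end)
      attr(out, "kind") <- "par"
      return(out)
    }
  }
  NULL
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_windows(run$windows, p("windows.tsv"))
  write_regions(run$regions, p("regions.tsv"))
  if (nrow(run$fates) > 0L) readr::write_tsv(run$fates, p("gene_fates.tsv"))
  if (!is.null(run$fate_summary)) readr::write_tsv(run$fate_summary, p("fate_summary.tsv"))
  for (i in seq_along(run$ztr)) {
    z <- run$ztr[[i]]
    write_fasta(setNames(
      z$wpseq$sequence,
      sprintf("W_ZTR_%d %d-%d n_variants=%d", i,
              z$wpseq$source_interval[1], z$wpseq$source_interval[2],
              nrow(z$wpseq$applied_variants))
    ), p(sprintf("w_pseudosequence_%d.fa", i)))
    readr::write_tsv(tibble::as_tibble(z$deletions), p(sprintf("w_deletions_%d.tsv", i)))
    readr::write_tsv(z$wpseq$coord_map, p(sprintf("coord_map_%d.tsv", i)))
  }
  writeLines(summary_text(run), p("summary.txt"))
  invisible(outdir)
}

summary_text <- function(run) {
  out <- c("ztrscan run summary", "===================", "")
  rg <- tidy(run$regions)
  out <- c(out, "Region calls:", utils::capture.output(print(as.data.frame(rg))), "")
  for (i in seq_along(run$ztr)) {
    g <- glance(run$ztr[[i]]$deletions)
    out <- c(out, sprintf(
      "ZTR %d: envelope %d bp, deleted %d bp, retained %d bp (%.1f Mb)",
      i, g$envelope_length, g$total_deleted, g$retained_length,
      g$retained_length / 1e6
    ))
  }
  if (!is.null(run$fate_summary)) {
    out <- c(out, "", "Gene fates:",
             utils::capture.output(print(as.data.frame(run$fate_summary))))
  }
  out
}

#' @export
print.ztr_run <- function(x, ...) {
  cat(summary_text(x), sep = "\n")
  invisible(x)
}

#' Compare a run against its planted truth
#'
#' Only available for simulated runs. Reports per-window label accuracy
#' (over retained windows, against the planted signature labels) and, for
#' each planted non-background region, whether a call of the right label
#' covers it within a tolerance of one window on each side.
#'
#' @param run a `ztr_run` from a simulated [run_pipeline()].
#' @param tolerance_windows envelope tolerance in windows; default 1.
#' @return A list: `window_accuracy`, `regions` tibble with
#'   `recovered` per planted region, `fates_match` tibble.
#' @export
evaluate_run <- function(run, tolerance_windows = 1L) {
  if (is.null(run$sim)) rlang::abort("evaluate_run() needs a simulated run")
  truth <- run$sim$truth
  wsize <- run$config$window_size
  tol <- tolerance_windows * wsize

  w <- run$windows
  key <- paste(w$chrom, w$start)
  tkey <- paste(truth$window_labels$chrom, truth$window_labels$start)
  tlab <- truth$window_labels$label[match(key, tkey)]
  ok <- !w$excluded & !is.na(tlab)
  window_accuracy <- mean(w$label[ok] == tlab[ok])

  planted <- truth$regions[truth$regions$class != "HEMIZYGOUS_Z", ]
  rec <- vapply(seq_len(nrow(planted)), function(i) {
    calls <- run$regions[run$regions$label == planted$class[i], ]
    any(abs(calls$start - planted$start[i]) <= tol &
          abs(calls$end - planted$end[i]) <= tol)
  }, logical(1))
  regions <- tibble::tibble(
    class = planted$class, start = planted$start, end = planted$end,
    recovered = rec
  )

  fates_match <- NULL
  if (nrow(run$fates) > 0L) {
    tf <- truth$gene_fates
    fates_match <- dplyr::left_join(run$fates[, c("name", "fate")],
                                    tf, by = "name", suffix = c("_called", "_true"))
    fates_match$match <- fates_match$fate_called == fates_match$fate_true
  }
  list(window_accuracy = window_accuracy, regions = regions,
       fates_match = fates_match)
}
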