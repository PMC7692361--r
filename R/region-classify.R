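# Window-level classification into ZTR / PAR / Z_DUP / HEMIZYGOUS_Z and
# merging of window labels into region calls with evidence.

#' Classification parameters
#'
#' Numeric thresholds for the coverage + SNP-density signatures. Coverage is
#' normalized so a two-copy (diploid-like) window sits at 1. A window's SNP
#' density is called elevated when it is at least
#' `max(k * lambda_bg, lambda_bg + 3 * sqrt(lambda_bg))`, i.e. both well
#' above the background level multiplicatively and outside its Poisson
#' noise band.
#'
#' @param cov_full normalized-coverage interval for a two-copy state;
#'   default `c(0.8, 1.25)`.
#' @param cov_hemi normalized-coverage interval for a one-copy
#'   (hemizygous) state; default `c(0.35, 0.65)`.
#' @param cov_dup_male_min minimum male normalized coverage for a Z-linked
#'   duplication; default 1.5.
#' @param density_elevation_factor multiplicative factor `k` over the
#'   background density; default 3.
#' @param min_run minimum number of consecutive windows per region call;
#'   default 2.
#' @return A `ztr_classify_params` list.
#' @export
classify_params <- function(cov_full = c(0.8, 1.25), cov_hemi = c(0.35, 0.65),
                            cov_dup_male_min = 1.5,
                            density_elevation_factor = 3, min_run = 2L) {
  stopifnot(
    length(cov_full) == 2L, length(cov_hemi) == 2L,
    density_elevation_factor > 1, min_run >= 1L
  )
  structure(
    list(
      cov_full = cov_full, cov_hemi = cov_hemi,
      cov_dup_male_min = cov_dup_male_min,
      density_elevation_factor = density_elevation_factor,
      min_run = as.integer(min_run)
    ),
    class = "ztr_classify_params"
  )
}

#' Join female and male window tables on a shared grid
#'
#' @param f_windows,m_windows window tables from the same chromosome grid,
#'   each carrying `norm_cov` and its sex's `snp_density_*` column.
#' @return One tibble with per-sex `norm_cov_f/m` and `snp_density_f/m`;
#'   a window is `excluded` if it is excluded in either sex.
#' @export
combine_sexes <- function(f_windows, m_windows) {
  f <- tibble::as_tibble(f_windows)
  m <- tibble::as_tibble(m_windows)
  same_grid <- nrow(f) == nrow(m) &&
    identical(f$chrom, m$chrom) &&
    identical(f$start, m$start) &&
    identical(f$end, m$end)
  if (!same_grid) rlang::abort("female and male window grids do not match")
  out <- tibble::tibble(
    chrom = f$chrom, start = f$start, end = f$end,
    excluded = f$excluded | m$excluded,
    norm_cov_f = f$norm_cov, norm_cov_m = m$norm_cov,
    snp_density_f = f$snp_density_f, snp_density_m = m$snp_density_m
  )
  class(out) <- c("ztr_windows", class(out))
  out
}

in_interval <- function(x, iv) !is.na(x) & x >= iv[1] & x <= iv[2]

density_elevation_threshold <- function(lambda_bg, k) {
  max(k * lambda_bg, lambda_bg + 3 * sqrt(lambda_bg))
}

#' Label windows by coverage and SNP-density signature
#'
#' Signatures (normalized coverage; density "elevated" relative to the
#' per-sex background level):
#' * `ZTR`: both sexes two-copy coverage, female density elevated, male not
#'   (the W-derived reads co-map onto the Z, doubling female coverage and
#'   adding female-only Z-W divergence heterozygosity).
#' * `PAR`: both sexes two-copy coverage, neither density elevated.
#' * `Z_DUP`: male coverage at least `cov_dup_male_min`, both densities
#'   elevated (paralogous sequence variants appear in both sexes).
#' * `HEMIZYGOUS_Z`: female one-copy coverage, male two-copy, female
#'   density not elevated.
#' * `AUTOSOME_LIKE` is reserved for declared baseline chromosomes.
#' * anything else: `UNCLASSIFIED`. Excluded windows are labelled
#'   `EXCLUDED` and skipped downstream.
#'
#' The per-sex background density `lambda_bg` is the median window SNP
#' density over baseline windows (declared via `baseline`, else all
#' retained windows).
#'
#' @param windows combined window table from [combine_sexes()] (or pass
#'   `f_windows` and `m_windows` separately).
#' @param params a [classify_params()] object.
#' @param baseline optional baseline declaration as in
#'   [normalize_coverage()], used to estimate `lambda_bg`.
#' @param autosome_chroms character vector of declared autosome-like
#'   (baseline) chromosome names.
#' @param m_windows optional male window table when `windows` is the
#'   female table.
#' @return `windows` with columns `label`, `f_elevated`, `m_elevated`;
#'   attribute `lambda_bg` records the per-sex background densities and
#'   elevation thresholds.
#' @export
classify_windows <- function(windows, params = classify_params(),
                             baseline = NULL, autosome_chroms = character(),
                             m_windows = NULL) {
  if (!is.null(m_windows)) windows <- combine_sexes(windows, m_windows)
  windows <- tibble::as_tibble(windows)
  retained <- !windows$excluded
  base_mask <- baseline_mask(windows, baseline) & retained
  declared <- !is.null(baseline) && any(base_mask)
  if (!any(base_mask)) base_mask <- retained
  # a declared baseline is candidate-free, so the efficient mean is used;
  # the all-windows fallback takes the median, which resists the candidate
  # regions themselves
  lambda_stat <- if (declared) mean else median
  lambda_f <- lambda_stat(windows$snp_density_f[base_mask])
  lambda_m <- lambda_stat(windows$snp_density_m[base_mask])
  k <- params$density_elevation_factor
  thr_f <- density_elevation_threshold(lambda_f, k)
  thr_m <- density_elevation_threshold(lambda_m, k)

  f_el <- windows$snp_density_f >= thr_f
  m_el <- windows$snp_density_m >= thr_m
  f_full <- in_interval(windows$norm_cov_f, params$cov_full)
  m_full <- in_interval(windows$norm_cov_m, params$cov_full)
  f_hemi <- in_interval(windows$norm_cov_f, params$cov_hemi)
  m_dup <- !is.na(windows$norm_cov_m) & windows$norm_cov_m >= params$cov_dup_male_min

  label <- rep("UNCLASSIFIED", nrow(windows))
  label[f_full & m_full & f_el & !m_el] <- "ZTR"
  label[f_full & m_full & !f_el & !m_el] <- "PAR"
  label[m_dup & f_el & m_el] <- "Z_DUP"
  label[f_hemi & m_full & !f_el] <- "HEMIZYGOUS_Z"
  label[windows$chrom %in% autosome_chroms] <- "AUTOSOME_LIKE"
  label[!retained] <- "EXCLUDED"

  windows$label <- label
  windows$f_elevated <- f_el
  windows$m_elevated <- m_el
  class(windows) <- unique(c("ztr_windows", class(windows)))
  attr(windows, "lambda_bg") <- list(
    female = lambda_f, male = lambda_m,
    threshold_female = thr_f, threshold_male = thr_m
  )
  windows
}

#' Merge window labels into region calls
#'
#' Maximal runs of identically-labelled windows become calls. A single
#' interior `UNCLASSIFIED` or `EXCLUDED` window flanked by the same label on
#' both sides is bridged so long calls are not fragmented by window noise.
#' Runs of `HEMIZYGOUS_Z` windows strictly between two `ZTR` runs are
#' absorbed into one ZTR envelope and recorded as candidate W-deletions
#' (consumed by [call_w_deletions()]). After envelope construction, runs
#' shorter than `min_run` are demoted to `UNCLASSIFIED`.
#'
#' @param labelled windows with a `label` column from [classify_windows()].
#' @param params a [classify_params()] object (`min_run` is used).
#' @param baseline optional baseline declaration; when given, each ZTR /
#'   Z_DUP call gets a one-sided [rank_sum_test()] p-value of its female
#'   (and male, for Z_DUP) window densities against the baseline windows.
#' @return A `ztr_regions` tibble: `chrom`, `start`, `end`, `label`,
#'   `n_windows`, per-sex mean coverage and density, `p_density_f`,
#'   `p_density_m`, and a `w_deletion_candidates` list column of candidate
#'   intervals.
#' @export
merge_calls <- function(labelled, params = classify_params(), baseline = NULL) {
  labelled <- tibble::as_tibble(labelled)
  # rank-sum evidence needs an explicit baseline declaration
  base_mask <- if (is.null(baseline)) rep(FALSE, nrow(labelled)) else {
    baseline_mask(labelled, baseline) & !labelled$excluded
  }
  out <- lapply(unique(labelled$chrom), function(ch) {
    w <- labelled[labelled$chrom == ch, ]
    merge_calls_one(w, params, labelled[base_mask, ])
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("ztr_regions", class(out))
  out
}

bridge_single_noise <- function(lab) {
  n <- length(lab)
  if (n < 3L) return(lab)
  orig <- lab
  for (i in 2:(n - 1L)) {
    if (orig[i] %in% c("UNCLASSIFIED", "EXCLUDED") &&
        orig[i - 1L] == orig[i + 1L] &&
        !orig[i - 1L] %in% c("UNCLASSIFIED", "EXCLUDED")) {
      lab[i] <- orig[i - 1L]
    }
  }
  lab
}

# demote runs shorter than min_run to UNCLASSIFIED, then re-bridge single
# interior noise windows; iterate to a fixed point so one misclassified
# window never fragments a long call
demote_and_bridge <- function(lab, min_run) {
  for (iter in 1:10) {
    before <- lab
    lab <- bridge_single_noise(lab)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (r$lengths[j] < min_run &&
          !r$values[j] %in% c("UNCLASSIFIED", "EXCLUDED", "HEMIZYGOUS_Z")) {
        lab[(ends[j] - r$lengths[j] + 1L):ends[j]] <- "UNCLASSIFIED"
      }
    }
    lab <- bridge_single_noise(lab)
    if (identical(lab, before)) break
  }
  lab
}

merge_calls_one <- function(w, params, baseline_windows) {
  n <- nrow(w)
  lab <- demote_and_bridge(w$label, params$min_run)
  r <- rle(lab)
  runs <- tibble::tibble(
    label = r$values,
    len = r$lengths,
    to = cumsum(r$lengths)
  )
  runs$from <- runs$to - runs$len + 1L
  runs$deletions <- vector("list", nrow(runs))

  # absorb HEMIZYGOUS_Z runs flanked by ZTR runs into one ZTR envelope
  repeat {
    hit <- NULL
    if (nrow(runs) >= 3L) {
      for (i in 2:(nrow(runs) - 1L)) {
        if (runs$label[i] == "HEMIZYGOUS_Z" &&
            runs$label[i - 1L] == "ZTR" && runs$label[i + 1L] == "ZTR") {
          hit <- i
          break
        }
      }
    }
    if (is.null(hit)) break
    i <- hit
    del <- c(w$start[runs$from[i]], w$end[runs$to[i]])
    merged <- tibble::tibble(
      label = "ZTR",
      len = runs$len[i - 1L] + runs$len[i] + runs$len[i + 1L],
      to = runs$to[i + 1L],
      from = runs$from[i - 1L],
      deletions = list(c(runs$deletions[[i - 1L]], list(del), runs$deletions[[i + 1L]]))
    )
    runs <- dplyr::bind_rows(
      runs[seq_len(i - 2L), ], merged,
      runs[seq(i + 2L, length.out = nrow(runs) - i - 1L), ]
    )
  }

  # demote short runs
  short <- runs$len < params$min_run &
    !runs$label %in% c("UNCLASSIFIED", "EXCLUDED")
  runs$label[short] <- "UNCLASSIFIED"
  runs$deletions[short] <- list(NULL)

  calls <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- seq(runs$from[i], runs$to[i])
    ww <- w[idx, ]
    p_f <- NA_real_
    p_m <- NA_real_
    if (runs$label[i] %in% c("ZTR", "Z_DUP") && nrow(baseline_windows) > 0L) {
      keep <- !ww$excluded
      if (any(keep)) {
        p_f <- rank_sum_test(ww$snp_density_f[keep],
                             baseline_windows$snp_density_f,
                             alternative = "greater")$p_value
        if (runs$label[i] == "Z_DUP") {
          p_m <- rank_sum_test(ww$snp_density_m[keep],
                               baseline_windows$snp_density_m,
                               alternative = "greater")$p_value
        }
      }
    }
    tibble::tibble(
      chrom = ww$chrom[1],
      start = ww$start[1],
      end = ww$end[nrow(ww)],
      label = runs$label[i],
      n_windows = length(idx),
      mean_norm_cov_f = mean(ww$norm_cov_f[!ww$excluded]),
      mean_norm_cov_m = mean(ww$norm_cov_m[!ww$excluded]),
      mean_density_f = mean(ww$snp_density_f[!ww$excluded]),
      mean_density_m = mean(ww$snp_density_m[!ww$excluded]),
      p_density_f = p_f,
      p_density_m = p_m,
      w_deletion_candidates = list(runs$deletions[[i]])
    )
  })
  dplyr::bind_rows(calls)
}

#' @export
tidy.ztr_regions <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_w_deletion_candidates <- vapply(out$w_deletion_candidates, length, integer(1))
  out$w_deletion_candidates <- NULL
  out
}

#' @export
glance.ztr_regions <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_ztr = sum(x$label == "ZTR"),
    n_par = sum(x$label == "PAR"),
    n_z_dup = sum(x$label == "Z_DUP"),
    ztr_bp = sum((x$end - x$start)[x$label == "ZTR"]),
    min_p_density_f = suppressWarnings(min(x$p_density_f, na.rm = TRUE))
  )
}
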