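# Per-site depth -> filtered, normalized per-window coverage statistics.

#' Remove sites with excessive depth
#'
#' Drops sites whose depth is strictly more than three times the average
#' depth, the standard guard against collapsed repeats inflating coverage.
#' Mapping-quality screening (MQ >= 60) is an upstream contract of the input
#' depth table and is not re-applied here.
#'
#' @param sites data frame with columns `chrom`, `pos` (1-based), `depth`,
#'   sorted by (chrom, pos) with at most one record per site.
#' @param mean_depth average depth used for the cutoff; when `NULL`
#'   (default) it is computed from the input table itself.
#' @param max_fold depth cutoff in multiples of `mean_depth`; default 3.
#' @return The retained sites as a tibble, with attributes `n_removed` and
#'   `mean_depth`.
#' @export
site_filter <- function(sites, mean_depth = NULL, max_fold = 3) {
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) == 0L) {
    rlang::warn("empty depth table")
    out <- sites
    attr(out, "n_removed") <- 0L
    attr(out, "mean_depth") <- NA_real_
    return(out)
  }
  if (is.null(mean_depth)) mean_depth <- mean(sites$depth)
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    rlang::abort("`mean_depth` must be positive")
  }
  keep <- sites$depth <= max_fold * mean_depth
  out <- sites[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "mean_depth") <- mean_depth
  out
}

#' Windowed coverage statistics
#'
#' Tiles each chromosome into consecutive non-overlapping windows of
#' `window_size` starting at coordinate 0 and computes, per window, the
#' number of covered sites (sites with a retained depth record) and the
#' arithmetic mean depth over those sites. A trailing partial window is
#' dropped. Windows with fewer than `min_covered_frac * window_size` covered
#' sites are flagged `excluded` (they stay in the table so the window grid
#' is always complete).
#'
#' @param sites retained sites from [site_filter()].
#' @param chrom_length length of the chromosome in bp; when `NULL` the last
#'   full window is inferred from the largest observed position.
#' @param window_size window width in bp; default 50,000.
#' @param min_covered_frac minimum covered fraction per retained window;
#'   default 0.6 (windows strictly below it are excluded).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `n_covered`, `mean_depth`, `excluded`.
#' @export
window_coverage <- function(sites, chrom_length = NULL, window_size = 50000L,
                            min_covered_frac = 0.6) {
  sites <- tibble::as_tibble(sites)
  window_size <- as.integer(window_size)
  chroms <- unique(sites$chrom)
  if (nrow(sites) > 0L && is.unsorted(sites$pos[sites$chrom == chroms[1]])) {
    rlang::abort("depth table must be sorted by position")
  }
  out <- lapply(chroms, function(ch) {
    s <- sites[sites$chrom == ch, ]
    len <- chrom_length %||% max(s$pos)
    n_win <- floor(len / window_size)
    if (n_win == 0L) {
      rlang::warn(sprintf("chromosome %s shorter than one window; no windows emitted", ch))
      return(NULL)
    }
    win <- (s$pos - 1L) %/% window_size # 0-based window index
    s <- s[win < n_win, ]
    win <- win[win < n_win]
    dt <- data.table::data.table(win = win, depth = s$depth)
    agg <- dt[, list(n_covered = .N, mean_depth = mean(depth)), by = "win"]
    full <- data.table::data.table(win = 0:(n_win - 1L))
    agg <- agg[full, on = "win"]
    agg[is.na(agg$n_covered), c("n_covered", "mean_depth") := list(0L, NA_real_)]
    data.table::setorderv(agg, "win")
    tibble::tibble(
      chrom = ch,
      start = agg$win * window_size,
      end = (agg$win + 1L) * window_size,
      n_covered = as.integer(agg$n_covered),
      mean_depth = agg$mean_depth,
      excluded = agg$n_covered < min_covered_frac * window_size
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("ztr_windows", class(out))
  out
}

#' Normalize window coverage against a baseline
#'
#' Divides each window's mean depth by the median mean depth over a set of
#' baseline windows, so a two-copy (diploid-like) window sits at 1. The
#' baseline is chosen in preference order: declared autosome-like windows,
#' then pseudoautosomal windows, then all retained windows of the
#' chromosome. The choice actually used is recorded in the `baseline`
#' attribute.
#'
#' @param windows window table from [window_coverage()].
#' @param baseline optional data frame of intervals (`chrom`, `start`,
#'   `end`) declaring baseline (autosome-like or PAR) windows, or a logical
#'   vector along `windows`; `NULL` falls back to all retained windows.
#' @param baseline_kind label recorded for provenance: `"autosome"`,
#'   `"par"`, or `"all"`.
#' @return `windows` with a `norm_cov` column; attribute `baseline` records
#'   the kind and the median depth used.
#' @export
normalize_coverage <- function(windows, baseline = NULL, baseline_kind = NULL) {
  windows <- tibble::as_tibble(windows)
  in_baseline <- baseline_mask(windows, baseline)
  kind <- baseline_kind %||% if (is.null(baseline)) "all" else "declared"
  base <- windows[in_baseline & !windows$excluded, ]
  if (nrow(base) == 0L) rlang::abort("no retained baseline windows")
  med <- median(base$mean_depth, na.rm = TRUE)
  if (!is.finite(med) || med == 0) rlang::abort("baseline median depth is zero")
  windows$norm_cov <- windows$mean_depth / med
  attr(windows, "baseline") <- list(kind = kind, median_depth = med,
                                    n_windows = nrow(base))
  class(windows) <- unique(c("ztr_windows", class(windows)))
  windows
}

baseline_mask <- function(windows, baseline) {
  if (is.null(baseline)) return(rep(TRUE, nrow(windows)))
  if (is.logical(baseline)) {
    if (length(baseline) != nrow(windows)) {
      rlang::abort("logical baseline must match the number of windows")
    }
    return(baseline)
  }
  baseline <- tibble::as_tibble(baseline)
  mask <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(baseline))) {
    hit <- windows$chrom == baseline$chrom[i] &
      windows$start >= baseline$start[i] &
      windows$end <= baseline$end[i]
    mask <- mask | hit
  }
  mask
}
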