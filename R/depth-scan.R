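# Sliding-window differential scan of sex-pooled read depth: per-individual
# window means per sex, absolute difference, Y-specific / X-like window
# classification, region merging and base-resolution breakpoint refinement.

#' Window parameters for the depth scan
#'
#' @param window Window width in bp (default 1000).
#' @param step Step between successive window starts in bp (default 500,
#'   i.e. half-overlapping windows); must satisfy `0 < step <= window`.
#' @return A list of class `window_params`.
#' @export
window_params <- function(window = 1000L, step = 500L) {
  window <- as.integer(window); step <- as.integer(step)
  if (!(step > 0L && step <= window)) stop("need 0 < step <= window")
  structure(list(window = window, step = step), class = "window_params")
}

#' Classification parameters for depth windows and refinement
#'
#' Thresholds are per-individual mean depths (pooled depth divided by pool
#' size), the natural unit of genomecov-style tracks: a Y-specific
#' (hemizygous, male-only) segment shows about half the per-individual depth
#' in males and near zero in females, while an X-like segment shows a
#' female:male per-individual ratio near 2.
#'
#' @param y_female_max_per_ind Maximum female per-individual window mean for a
#'   Y-specific call ("almost complete absence" of female reads; default 0.1).
#' @param y_male_min_per_ind Minimum male per-individual window mean for a
#'   Y-specific call (default 2.0).
#' @param x_ratio_band Two-element numeric: female:male per-individual ratio
#'   band for an X-like call (default `c(1.6, 2.4)` around the 2-fold
#'   signature).
#' @param x_male_min_per_ind Minimum male per-individual window mean for an
#'   X-like call (default 2.0).
#' @param merge_max_gap Maximum gap in bp between same-class windows merged
#'   into one region; defaults to the scan step so that regions separated by
#'   one unlabeled window stay separate.
#' @param y_female_abs_base Maximum pooled female depth a base may have inside
#'   a refined Y-specific interval (default 0).
#' @param ratio_smooth Width in bp of the centered running-median smoother
#'   applied to the per-base ratio during X-like refinement (odd; default 51).
#' @return A list of class `classify_params`.
#' @export
classify_params <- function(y_female_max_per_ind = 0.1,
                            y_male_min_per_ind = 2.0,
                            x_ratio_band = c(1.6, 2.4),
                            x_male_min_per_ind = 2.0,
                            merge_max_gap = NULL,
                            y_female_abs_base = 0,
                            ratio_smooth = 51L) {
  stopifnot(length(x_ratio_band) == 2L, x_ratio_band[1] < x_ratio_band[2],
            ratio_smooth >= 1L)
  structure(list(y_female_max_per_ind = y_female_max_per_ind,
                 y_male_min_per_ind = y_male_min_per_ind,
                 x_ratio_band = x_ratio_band,
                 x_male_min_per_ind = x_male_min_per_ind,
                 merge_max_gap = merge_max_gap,
                 y_female_abs_base = y_female_abs_base,
                 ratio_smooth = as.integer(ratio_smooth)),
            class = "classify_params")
}

window_starts <- function(L, step) seq.int(0L, L - 1L, by = step)

#' Windowed per-individual depth means and their absolute difference
#'
#' Slides half-open windows `[0, w), [s, s + w), ...` (starts while `< L`,
#' truncated at `L`) over a chromosome and, within each window, averages the
#' pooled depth of each sex over the positions used, then divides by the pool
#' size. Positions with zero pooled depth in both sexes are ignored; windows
#' in which every position is zero in both sexes get `NA` means and are
#' excluded from classification.
#'
#' @param male,female [depth_track()]s for the two sex pools on the same
#'   chromosome (equal length).
#' @param params A [window_params()].
#' @return Data frame with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), `n_positions_used`, `mean_per_ind_male`,
#'   `mean_per_ind_female`, `abs_diff`, `ratio_f_over_m` (`NA` when the male
#'   mean is 0 or no position was used).
#' @export
window_scan <- function(male, female, params = window_params()) {
  stopifnot(inherits(male, "depth_track"), inherits(female, "depth_track"))
  if (male$chrom != female$chrom || length(male$depth) != length(female$depth))
    stop("male and female tracks must cover the same chromosome and length")
  if (male$n_individuals < 1L || female$n_individuals < 1L)
    stop("zero-size pool")
  L <- length(male$depth)
  used <- male$depth > 0 | female$depth > 0
  cm <- c(0, cumsum(male$depth))
  cf <- c(0, cumsum(female$depth))
  cu <- c(0, cumsum(used))
  start <- window_starts(L, params$step)
  end <- pmin(start + params$window, L)
  n_used <- cu[end + 1L] - cu[start + 1L]
  sum_m <- cm[end + 1L] - cm[start + 1L]
  sum_f <- cf[end + 1L] - cf[start + 1L]
  mean_m <- ifelse(n_used > 0, sum_m / n_used / male$n_individuals, NA_real_)
  mean_f <- ifelse(n_used > 0, sum_f / n_used / female$n_individuals, NA_real_)
  ratio <- ifelse(!is.na(mean_m) & mean_m > 0, mean_f / mean_m, NA_real_)
  data.frame(chrom = male$chrom, start = start, end = end,
             n_positions_used = as.integer(n_used),
             mean_per_ind_male = mean_m, mean_per_ind_female = mean_f,
             abs_diff = abs(mean_m - mean_f), ratio_f_over_m = ratio,
             stringsAsFactors = FALSE)
}

#' Label depth windows as Y-specific or X-like
#'
#' A window is `Y_specific` when the female per-individual mean is at most
#' `y_female_max_per_ind` and the male mean at least `y_male_min_per_ind`;
#' otherwise it is `X_like` when the male mean is at least
#' `x_male_min_per_ind` and the female:male ratio falls inside `x_ratio_band`.
#' Labels are mutually exclusive (Y is tested first); all other windows —
#' including windows with no used position — are left unlabeled (`NA`).
#'
#' @param stats Output of [window_scan()].
#' @param params A [classify_params()].
#' @return `stats` with an added `region_class` column.
#' @export
classify_windows <- function(stats, params = classify_params()) {
  m <- stats$mean_per_ind_male
  f <- stats$mean_per_ind_female
  r <- stats$ratio_f_over_m
  defined <- stats$n_positions_used > 0 & !is.na(m) & !is.na(f)
  y <- defined & f <= params$y_female_max_per_ind & m >= params$y_male_min_per_ind
  x <- defined & !y & m >= params$x_male_min_per_ind & !is.na(r) &
    r >= params$x_ratio_band[1] & r <= params$x_ratio_band[2]
  stats$region_class <- ifelse(y, "Y_specific", ifelse(x, "X_like", NA))
  stats
}

#' Merge same-class windows into regions
#'
#' Unions, per chromosome and class, labeled windows whose intervals overlap
#' or lie within `merge_max_gap` of each other; classes never merge with each
#' other. Region summaries are the means of the member windows' statistics.
#'
#' @param labeled Output of [classify_windows()], sorted by (chrom, start).
#' @param params A [classify_params()]; `merge_max_gap = NULL` defaults to
#'   the scan step (500 bp), so same-class windows bridge half-window holes
#'   but regions separated by a full unlabeled window stay separate.
#' @param default_gap Gap used when `params$merge_max_gap` is `NULL`.
#' @return Data frame of class calls at window resolution: `chrom`, `start`,
#'   `end`, `region_class`, `n_windows`, `mean_per_ind_male`,
#'   `mean_per_ind_female`, `mean_ratio`.
#' @export
merge_regions <- function(labeled, params = classify_params(),
                          default_gap = 500L) {
  lab <- labeled[!is.na(labeled$region_class), , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      region_class = character(), n_windows = integer(),
                      mean_per_ind_male = numeric(),
                      mean_per_ind_female = numeric(), mean_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(lab)) return(empty)
  if (is.unsorted(order(lab$chrom, lab$start))) stop("windows must be sorted")
  gap <- if (is.null(params$merge_max_gap)) as.integer(default_gap)
         else as.integer(params$merge_max_gap)
  pieces <- lapply(split(seq_len(nrow(lab)),
                         list(lab$chrom, lab$region_class), drop = TRUE),
                   function(idx) {
    w <- lab[idx, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    new_grp <- c(TRUE, w$start[-1L] > cummax(w$end[-nrow(w)]) + gap)
    grp <- cumsum(new_grp)
    do.call(rbind, lapply(split(seq_len(nrow(w)), grp), function(j) {
      data.frame(chrom = w$chrom[1L], start = min(w$start[j]),
                 end = max(w$end[j]), region_class = w$region_class[1L],
                 n_windows = length(j),
                 mean_per_ind_male = mean(w$mean_per_ind_male[j]),
                 mean_per_ind_female = mean(w$mean_per_ind_female[j]),
                 mean_ratio = mean(w$ratio_f_over_m[j]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$region_class), , drop = FALSE]
}

# cummax over previous ends needs the vector lagged; guard the 1-row case
# (w$end[-nrow(w)] is length 0 there and the c(TRUE, ...) above handles it).

# Maximal run of TRUE in a logical vector; leftmost-longest tie-break.
# Returns c(start_index, end_index_exclusive) in 1-based indexing, or NULL.
longest_run <- function(ok) {
  if (!length(ok) || !any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]  # which.max is leftmost on ties
  c(starts[best], ends[best] + 1L)
}

# Centered running median, width k (odd), Tukey endpoint rule; NA-safe by
# treating NA as out-of-band sentinel after smoothing.
smooth_ratio <- function(f, m, k) {
  ratio <- ifelse(m > 0, f / m, NA_real_)
  if (k <= 1L) return(ratio)
  if (k %% 2L == 0L) k <- k + 1L
  filled <- ratio
  filled[is.na(filled)] <- -1
  if (length(filled) < k) return(ratio)
  out <- stats::runmed(filled, k, endrule = "median")
  out[out < 0] <- NA_real_
  out
}

#' Refine region boundaries to base resolution
#'
#' Searches the region extended by up to one window beyond each edge. For a
#' `Y_specific` region the refined interval is the maximal run of consecutive
#' positions with pooled female depth at most `y_female_abs_base` and pooled
#' male depth at least 1. For an `X_like` region it is the maximal run where
#' the per-base per-individual female:male ratio, smoothed by a centered
#' running median of width `ratio_smooth`, lies inside `x_ratio_band`. Ties
#' are broken leftmost-longest. Regions with no qualifying position get `NA`
#' refined bounds.
#'
#' @param regions Output of [merge_regions()] (or a subset).
#' @param male,female [depth_track()]s at base resolution.
#' @param params A [classify_params()].
#' @param wparams A [window_params()] (controls the search padding).
#' @return `regions` with added `refined_start`, `refined_end` (0-based
#'   half-open) and `refined_length` columns.
#' @export
refine_breakpoints <- function(regions, male, female,
                               params = classify_params(),
                               wparams = window_params()) {
  L <- length(male$depth)
  n <- nrow(regions)
  rs <- re <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    lo <- max(0L, regions$start[i] - wparams$window)
    hi <- min(L, regions$end[i] + wparams$window)
    idx <- (lo + 1L):hi                       # 1-based into depth arrays
    if (regions$region_class[i] == "Y_specific") {
      ok <- female$depth[idx] <= params$y_female_abs_base &
        male$depth[idx] >= 1
    } else {
      sm <- smooth_ratio(female$depth[idx] / female$n_individuals,
                         male$depth[idx] / male$n_individuals,
                         params$ratio_smooth)
      ok <- !is.na(sm) & sm >= params$x_ratio_band[1] &
        sm <= params$x_ratio_band[2]
    }
    run <- longest_run(ok)
    if (!is.null(run)) {
      rs[i] <- lo + run[1L] - 1L
      re[i] <- lo + run[2L] - 1L
    }
  }
  regions$refined_start <- rs
  regions$refined_end <- re
  regions$refined_length <- re - rs
  regions
}

# Base-resolution X-like search in the padded neighborhood of a refined
# Y-specific region. A sub-window X segment (shorter than ~3/4 of the window)
# can never satisfy the window-level ratio band because the flanking sequence
# dilutes the window mean, but it sits at a Y breakpoint by construction of
# the X/Y architecture, so it is recoverable by the same smoothed-ratio run
# criterion the X refinement uses.
rescue_x_near_y <- function(regions, male, female, params, wparams) {
  ys <- which(regions$region_class == "Y_specific" &
              !is.na(regions$refined_start))
  found <- list()
  L <- length(male$depth)
  for (i in ys) {
    for (side in c("left", "right")) {
      if (side == "left") {
        lo <- max(0L, regions$refined_start[i] - wparams$window)
        hi <- regions$refined_start[i]
      } else {
        lo <- regions$refined_end[i]
        hi <- min(L, regions$refined_end[i] + wparams$window)
      }
      if (hi - lo < params$ratio_smooth) next
      idx <- (lo + 1L):hi
      sm <- smooth_ratio(female$depth[idx] / female$n_individuals,
                         male$depth[idx] / male$n_individuals,
                         params$ratio_smooth)
      mean_ok <- male$depth[idx] / male$n_individuals >=
        params$x_male_min_per_ind
      ok <- !is.na(sm) & sm >= params$x_ratio_band[1] &
        sm <= params$x_ratio_band[2] & mean_ok
      run <- longest_run(ok)
      if (is.null(run) || run[2L] - run[1L] < params$ratio_smooth) next
      s <- lo + run[1L] - 1L
      e <- lo + run[2L] - 1L
      pos <- (s + 1L):e
      mm <- mean(male$depth[pos]) / male$n_individuals
      ff <- mean(female$depth[pos]) / female$n_individuals
      found[[length(found) + 1L]] <-
        data.frame(chrom = regions$chrom[i], start = s, end = e,
                   region_class = "X_like", n_windows = 0L,
                   mean_per_ind_male = mm, mean_per_ind_female = ff,
                   mean_ratio = ff / mm, refined_start = s, refined_end = e,
                   refined_length = e - s, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) return(regions[0, , drop = FALSE])
  out <- do.call(rbind, found)
  # drop rescues overlapping an existing X_like call
  xs <- regions[regions$region_class == "X_like", , drop = FALSE]
  if (nrow(xs)) {
    keep <- vapply(seq_len(nrow(out)), function(k)
      !any(xs$chrom == out$chrom[k] & xs$start < out$end[k] &
             xs$end > out$start[k]), logical(1))
    out <- out[keep, , drop = FALSE]
  }
  unique(out)
}

#' Full depth-scan pipeline for one chromosome
#'
#' Runs [window_scan()], [classify_windows()] and [merge_regions()], then
#' (optionally) [refine_breakpoints()]. When refining, the padded
#' neighborhood of each refined Y-specific region is additionally searched
#' for X-like segments at base resolution: an X segment much shorter than the
#' window cannot pass the window-level ratio band (the flanks dilute the
#' window mean), but it adjoins a Y breakpoint by construction of the X/Y
#' architecture and is recovered there by the same smoothed-ratio criterion.
#'
#' @param male,female [depth_track()]s for the two sex pools.
#' @param wparams A [window_params()].
#' @param cparams A [classify_params()].
#' @param refine Refine breakpoints to base resolution? (default `TRUE`)
#' @return List of class `depth_scan` with `windows` (labeled window stats)
#'   and `regions` (region calls, refined when requested).
#' @export
depth_scan <- function(male, female, wparams = window_params(),
                       cparams = classify_params(), refine = TRUE) {
  stats <- window_scan(male, female, wparams)
  labeled <- classify_windows(stats, cparams)
  regions <- merge_regions(labeled, cparams, default_gap = wparams$step)
  if (refine && nrow(regions)) {
    regions <- refine_breakpoints(regions, male, female, cparams, wparams)
    rescued <- rescue_x_near_y(regions, male, female, cparams, wparams)
    if (nrow(rescued)) {
      regions <- rbind(regions, rescued)
      regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
      rownames(regions) <- NULL
    }
  }
  structure(list(windows = labeled, regions = regions,
                 wparams = wparams, cparams = cparams),
            class = "depth_scan")
}

#' @export
print.depth_scan <- function(x, ...) {
  cat(sprintf("Depth scan: %d windows, %d region call(s)\n",
              nrow(x$windows), nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Genome-wide per-window absolute depth differential
#'
#' One row per window with the absolute difference between the male and
#' female per-individual window means — the quantity whose genome-wide
#' maxima flag candidate sex-linked regions.
#'
#' @param stats Output of [window_scan()] (one or several chromosomes,
#'   row-bound).
#' @return Data frame `chrom`, `start`, `end`, `abs_diff`, sorted by
#'   (chrom, start).
#' @export
depth_differential_report <- function(stats) {
  out <- stats[, c("chrom", "start", "end", "abs_diff")]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot the per-window depth differential along a chromosome
#'
#' @param report Output of [depth_differential_report()] (one chromosome).
#' @param ... Passed to [graphics::plot()].
#' @return `report`, invisibly.
#' @export
plot_depth_differential <- function(report, ...) {
  mid <- (report$start + report$end) / 2
  graphics::plot(mid, report$abs_diff, type = "h",
                 xlab = sprintf("position on %s (bp)", report$chrom[1L]),
                 ylab = "|male - female| per-individual depth", ...)
  invisible(report)
}
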