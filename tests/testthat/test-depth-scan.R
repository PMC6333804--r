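test_that("window enumeration matches the brute-force oracle", {
  got <- window_scan(constant_track("c1", 2000L, 4, 2, "male"),
                     constant_track("c1", 2000L, 4, 2, "female"))
  expect_equal(got$start, c(0L, 500L, 1000L, 1500L))
  expect_equal(got$end, c(1000L, 1500L, 2000L, 2000L))

  set.seed(51)
  for (i in 1:100) {
    L <- sample(50:5000, 1)
    w <- sample(10:1000, 1)
    s <- sample(seq_len(w), 1)
    wp <- window_params(window = w, step = s)
    got <- window_scan(constant_track("c1", L, 1, 1, "male"),
                       constant_track("c1", L, 1, 1, "female"), wp)
    want <- oracle_windows(L, w, s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("per-individual means, zero-position handling and abs_diff", {
  # pooled 490 over 49 males vs 530 over 53 females -> per-ind 10 vs 10
  st <- window_scan(constant_track("c1", 1500L, 490, 49, "male"),
                    constant_track("c1", 1500L, 530, 53, "female"))
  expect_equal(st$mean_per_ind_male, rep(10, 3))
  expect_equal(st$mean_per_ind_female, rep(10, 3))
  expect_equal(st$abs_diff, rep(0, 3))
  expect_equal(st$ratio_f_over_m, rep(1, 3))

  # positions dark in both sexes are excluded; all-dark windows undefined
  m <- c(rep(8, 500), rep(0, 1000))
  f <- c(rep(4, 500), rep(0, 500), rep(8, 500))
  st <- window_scan(depth_track("c1", m, 2, "male"),
                    depth_track("c1", f, 2, "female"),
                    window_params(500L, 500L))
  expect_equal(st$n_positions_used, c(500L, 0L, 500L))
  expect_true(is.na(st$mean_per_ind_male[2]))
  expect_equal(st$mean_per_ind_male[c(1, 3)], c(4, 0))
  expect_equal(st$ratio_f_over_m[1], 0.5)
  expect_true(is.na(st$ratio_f_over_m[3]))  # male mean 0: ratio undefined

  expect_error(window_scan(constant_track("c1", 10L, 1, 1, "male"),
                           constant_track("c1", 20L, 1, 1, "female")),
               "same chromosome")
})

test_that("windowed means aggregate back to the genome mean", {
  set.seed(61)
  L <- 4096L
  m <- depth_track("c1", rpois(L, 12) + 1, 3, "male")
  f <- depth_track("c1", rpois(L, 20) + 1, 5, "female")
  st <- window_scan(m, f, window_params(256L, 256L))  # non-overlapping
  agg <- sum(st$mean_per_ind_male * st$n_positions_used) /
    sum(st$n_positions_used)
  expect_lt(abs(agg - mean(m$depth) / 3), 1e-9)
})

test_that("window labels follow the thresholds and their scaling behavior", {
  lab1 <- classify_windows(data.frame(chrom = "c1", start = 0L, end = 1000L,
                                      n_positions_used = 1000L,
                                      mean_per_ind_male = 7.5,
                                      mean_per_ind_female = 0.02,
                                      abs_diff = 7.48,
                                      ratio_f_over_m = 0.02 / 7.5))
  expect_equal(lab1$region_class, "Y_specific")

  lab2 <- classify_windows(data.frame(chrom = "c1", start = 0L, end = 1000L,
                                      n_positions_used = 1000L,
                                      mean_per_ind_male = 10,
                                      mean_per_ind_female = 20, abs_diff = 10,
                                      ratio_f_over_m = 2))
  expect_equal(lab2$region_class, "X_like")

  same <- classify_windows(data.frame(chrom = "c1", start = 0L, end = 1000L,
                                      n_positions_used = 1000L,
                                      mean_per_ind_male = 10,
                                      mean_per_ind_female = 10, abs_diff = 0,
                                      ratio_f_over_m = 1))
  expect_true(is.na(same$region_class))

  # ratio-based X labels survive a common rescaling; absolute Y labels do not
  mk <- function(m_depth, f_depth, scale) {
    window_scan(constant_track("c1", 1000L, m_depth * scale, 2, "male"),
                constant_track("c1", 1000L, f_depth * scale, 2, "female"),
                window_params(1000L, 1000L))
  }
  expect_equal(classify_windows(mk(6, 0.1, 1))$region_class, "Y_specific")
  expect_true(is.na(classify_windows(mk(6, 0.1, 0.5))$region_class))
  expect_equal(classify_windows(mk(8, 16, 1))$region_class, "X_like")
  expect_equal(classify_windows(mk(8, 16, 0.5))$region_class, "X_like")
})

test_that("same-class regions merge like the base-marking union oracle", {
  lab <- data.frame(chrom = "c1", start = c(0L, 500L, 2000L),
                    end = c(1000L, 1500L, 3000L),
                    n_positions_used = 1000L, mean_per_ind_male = 8,
                    mean_per_ind_female = 0.01, abs_diff = 8,
                    ratio_f_over_m = 0,
                    region_class = c("Y_specific", "Y_specific", "X_like"))
  reg <- merge_regions(lab, classify_params(merge_max_gap = 0L))
  expect_equal(reg$start, c(0L, 2000L))
  expect_equal(reg$end, c(1500L, 3000L))
  expect_equal(reg$region_class, c("Y_specific", "X_like"))

  set.seed(71)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    starts <- sort(sample(seq(0L, 5000L, by = 100L), n))
    lens <- sample(c(100L, 300L, 700L), n, replace = TRUE)
    gap <- sample(c(0L, 100L, 500L), 1)
    lab <- data.frame(chrom = "c1", start = starts, end = starts + lens,
                      n_positions_used = 100L, mean_per_ind_male = 8,
                      mean_per_ind_female = 0.01, abs_diff = 8,
                      ratio_f_over_m = 0, region_class = "Y_specific")
    got <- merge_regions(lab, classify_params(merge_max_gap = gap))
    want <- oracle_union(starts, starts + lens, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("breakpoint refinement finds maximal runs with leftmost ties", {
  # all bases qualify -> refined interval is the padded search interval
  L <- 3000L
  m <- constant_track("c1", L, 8, 2, "male")
  f <- constant_track("c1", L, 0, 2, "female")
  reg <- data.frame(chrom = "c1", start = 1000L, end = 2000L,
                    region_class = "Y_specific")
  got <- refine_breakpoints(reg, m, f)
  expect_equal(c(got$refined_start, got$refined_end), c(0L, 3000L))

  # one interior female-covered base splits the run; longest side wins,
  # leftmost on ties
  f2 <- f; f2$depth[1500] <- 3  # 0-based 1499: runs of 1499 vs 1500 bases
  got <- refine_breakpoints(reg, m, f2)
  expect_equal(c(got$refined_start, got$refined_end), c(1500L, 3000L))
  f3 <- f; f3$depth[1501] <- 3  # 0-based 1500: runs of 1500 vs 1499 bases
  got <- refine_breakpoints(reg, m, f3)
  expect_equal(c(got$refined_start, got$refined_end), c(0L, 1500L))
  f4 <- f; f4$depth[c(1001, 2002)] <- 3  # two 1000-base runs -> leftmost
  got <- refine_breakpoints(reg, m, f4)
  expect_equal(c(got$refined_start, got$refined_end), c(0L, 1000L))

  # no qualifying base -> absent refined interval
  got <- refine_breakpoints(reg, m, constant_track("c1", L, 5, 2, "female"))
  expect_true(is.na(got$refined_start))
})

test_that("the differential report is deterministic and linear in depth", {
  set.seed(81)
  m <- depth_track("c1", rpois(3000L, 30), 2, "male")
  f <- depth_track("c1", rpois(3000L, 10), 2, "female")
  st <- window_scan(m, f)
  rep1 <- depth_differential_report(st)
  expect_equal(rep1$start, sort(rep1$start))

  m2 <- depth_track("c1", m$depth * 2, 2, "male")
  f2 <- depth_track("c1", f$depth * 2, 2, "female")
  rep2 <- depth_differential_report(window_scan(m2, f2))
  expect_equal(rep2$abs_diff, rep1$abs_diff * 2)

  same <- depth_differential_report(window_scan(m, m))
  expect_true(all(same$abs_diff == 0))
})

test_that("the depth pipeline recovers the planted architecture", {
  cfg <- small_cfg()
  dep <- simulate_depth(cfg)
  ds <- depth_scan(dep$male, dep$female)
  tr <- dep$truth
  y <- ds$regions[ds$regions$region_class == "Y_specific", ]
  x <- ds$regions[ds$regions$region_class == "X_like", ]
  expect_equal(nrow(y), 1L)
  expect_equal(nrow(x), 1L)
  expect_equal(y$refined_start, unname(tr$y_interval["start"]))
  expect_equal(y$refined_end, unname(tr$y_interval["end"]))
  expect_equal(x$refined_start, unname(tr$x_interval["start"]))
  expect_equal(x$refined_end, unname(tr$x_interval["end"]))

  # genome-wide maximal differential overlaps the planted Y insertion
  rep_ <- depth_differential_report(window_scan(dep$male, dep$female))
  top <- rep_[which.max(rep_$abs_diff), ]
  expect_lt(top$start, tr$y_interval["end"])
  expect_gt(top$end, tr$y_interval["start"])

  # with Poisson noise the merged Y call still overlaps truth at Jaccard >= 0.8
  depn <- simulate_depth(small_cfg(noise_mode = "poisson"))
  dsn <- depth_scan(depn$male, depn$female)
  yn <- dsn$regions[dsn$regions$region_class == "Y_specific", ][1, ]
  inter <- min(yn$refined_end, tr$y_interval["end"]) -
    max(yn$refined_start, tr$y_interval["start"])
  uni <- max(yn$refined_end, tr$y_interval["end"]) -
    min(yn$refined_start, tr$y_interval["start"])
  expect_gte(inter / uni, 0.8)
})
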