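test_that("configuration defaults mirror the study geometry and validate", {
  cfg <- sim_config()
  expect_equal(cfg$n_males, 49L)
  expect_equal(cfg$n_females, 53L)
  expect_equal(cfg$y_length, 9149L)
  expect_equal(cfg$x_length, 425L)
  expect_length(cfg$sex_linked_snps, 9L)
  expect_lte(diff(range(cfg$sex_linked_snps)), 15000L)
  expect_error(sim_config(y_start = 999000L), "chrom_length|>=")
  expect_error(sim_config(sex_linked_snps = c(500500L)), "outside the Y/X")
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 13L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_fixture(cfg, d1)
  p2 <- simulate_fixture(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # a different seed changes the reference
  other <- simulate_reference(small_cfg(seed = 14L))
  expect_false(identical(as.character(other$reference),
                         as.character(simulate_reference(cfg)$reference)))
})

test_that("haplotypes share flanks and differ by the planted insertion", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  w <- stats::setNames(Biostrings::width(ref$haplotypes),
                       names(ref$haplotypes))
  expect_equal(unname(w["Y_haplotype"] - w["X_haplotype"]),
               cfg$y_length - cfg$x_length)
  xh <- as.character(ref$haplotypes[["X_haplotype"]])
  yh <- as.character(ref$haplotypes[["Y_haplotype"]])
  expect_equal(substr(xh, 1, cfg$y_start), substr(yh, 1, cfg$y_start))
  expect_equal(substr(xh, cfg$y_start + cfg$x_length + 1, nchar(xh)),
               substr(yh, cfg$y_start + cfg$y_length + 1, nchar(yh)))
  # degenerate zero-length X segment: pure insertion architecture
  pure <- simulate_reference(small_cfg(x_length = 0L))
  wp <- stats::setNames(Biostrings::width(pure$haplotypes),
                        names(pure$haplotypes))
  expect_equal(unname(wp["Y_haplotype"] - wp["X_haplotype"]), 3000L)
  # default geometry reproduces the printed length difference
  expect_equal(sim_config()$y_length - sim_config()$x_length, 9149L - 425L)
})

test_that("planted genotypes are strictly sex-linked and mirror under swap", {
  cfg <- small_cfg()
  gen <- simulate_genotypes(cfg)
  planted <- gen$variants$pos %in% cfg$sex_linked_snps
  pat <- classify_variant(gen$variants, gen$cohort, scan_params())
  expect_true(all(pat$system_called[planted] == "XY"))

  swapped <- sexed_cohort(gen$cohort$sample,
                          ifelse(gen$cohort$sex == "male", "female", "male"))
  pat_zw <- classify_variant(gen$variants, swapped, scan_params(system = "ZW"))
  expect_true(all(pat_zw$system_called[planted] == "ZW"))

  # heavy genotype error destroys perfect linkage
  noisy <- simulate_genotypes(small_cfg(genotype_error_rate = 0.5))
  pat_n <- classify_variant(noisy$variants, noisy$cohort, scan_params())
  planted_n <- noisy$variants$pos %in% cfg$sex_linked_snps
  expect_lt(sum(pat_n$system_called[planted_n] == "XY"), sum(planted_n))
})

test_that("depth expectations follow the hemizygosity model", {
  cfg <- small_cfg()  # noise off
  dep <- simulate_depth(cfg)
  tr <- dep$truth
  yi <- (tr$y_interval["start"] + 1):tr$y_interval["end"]
  xi <- (tr$x_interval["start"] + 1):tr$x_interval["end"]
  expect_true(all(dep$female$depth[yi] == 0))
  expect_true(all(dep$male$depth[yi] == cfg$n_males * cfg$lambda / 2))
  ratio_x <- (mean(dep$female$depth[xi]) / cfg$n_females) /
    (mean(dep$male$depth[xi]) / cfg$n_males)
  expect_equal(ratio_x, 2)

  # Poisson mode: flank per-individual mean within 3 standard errors
  depn <- simulate_depth(small_cfg(noise_mode = "poisson"))
  flank <- seq_len(cfg$y_start)
  per_ind <- mean(depn$male$depth[flank]) / cfg$n_males
  se <- sqrt(cfg$lambda / (cfg$n_males * length(flank)))
  expect_lt(abs(per_ind - cfg$lambda), 3 * se)
  # female leak shows up in the Y interval when requested
  leaky <- simulate_depth(small_cfg(noise_mode = "poisson",
                                    female_leak_rate = 0.2))
  expect_gt(mean(leaky$female$depth[yi]), 0)
})

test_that("generated copy labels are reproduced by the classifier", {
  cfg <- small_cfg()
  feats <- simulate_sequences_for_features(cfg)
  got <- classify_copy(feats$cds)
  expect_equal(got$functional, feats$labels$functional)
  expect_true(all(got$premature_stop[feats$labels$lesion == "premature_stop"]))
  expect_true(all(got$frameshift_flag[feats$labels$lesion == "frameshift"]))
  expect_false(any(got$premature_stop[feats$labels$lesion == "none"]))
  expect_false(any(got$frameshift_flag[feats$labels$lesion == "none"]))
})

test_that("fixture files re-read losslessly through the readers", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  paths <- simulate_fixture(cfg, dir)
  gen <- simulate_genotypes(cfg)
  dep <- simulate_depth(cfg)

  cohort <- read_sample_sheet(paths$cohort)
  expect_equal(cohort$sample, gen$cohort$sample)
  expect_equal(cohort$sex, gen$cohort$sex)

  vs <- read_vcf(paths$vcf, cohort)
  expect_equal(vs$pos, gen$variants$pos)
  expect_equal(unname(vs$geno), unname(gen$variants$geno))

  lens <- stats::setNames(cfg$chrom_length, cfg$chrom)
  m <- read_depth_track(paths$male_depth, lens, "male", cfg$n_males)[[1]]
  f <- read_depth_track(paths$female_depth, lens, "female",
                        cfg$n_females)[[1]]
  expect_identical(m$depth, dep$male$depth)
  expect_identical(f$depth, dep$female$depth)

  primers <- read_primer_set(paths$primers)
  expect_equal(sort(primers$role),
               sort(c("forward_common", "forward_y", "reverse_common")))
})

test_that("the full pipeline recovers the planted locus end to end", {
  cfg <- small_cfg()
  gen <- simulate_genotypes(cfg)
  dep <- simulate_depth(cfg)
  sc <- scan_sex_linked(gen$variants, gen$cohort)
  ds <- depth_scan(dep$male, dep$female)
  cand <- integrate_candidates(sc$clusters, ds$regions)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$has_snp_cluster & cand$has_Y_region & cand$has_X_region)
  y <- ds$regions[ds$regions$region_class == "Y_specific", ]
  x <- ds$regions[ds$regions$region_class == "X_like", ]
  expect_equal(unname(c(y$refined_start, y$refined_end)),
               unname(dep$truth$y_interval))
  expect_equal(unname(c(x$refined_start, x$refined_end)),
               unname(dep$truth$x_interval))
})
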