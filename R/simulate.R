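# Seeded synthetic-data generator emulating the study architecture: a diploid
# cohort in which males carry a hemizygous Y-specific insertion and one copy
# of a short X-specific segment, females two X copies; fully sex-linked SNPs
# flank the insertion; autosomal SNPs segregate under HWE; per-base pooled
# coverage is Poisson. Ground truth is emitted for recovery tests.
#
# The scan reference is a hybrid chromosome carrying the Y-sequence and the
# X-sequence side by side — the situation the depth scan is designed to
# detect, where an assembly conflates both haplotypes so that males map at
# half per-individual depth on both segments, females at zero on Y and full
# depth on X.

#' Simulation scenario configuration
#'
#' Defaults mirror the study geometry: a 9,149 bp male-specific Y insertion
#' adjoined by a 425 bp X-specific segment on a 1 Mb chromosome, nine fully
#' sex-linked SNPs spanning under 15 kb around the insertion, a cohort of 49
#' males and 53 females, and a per-individual coverage of 15x (the study's
#' per-sample range was 12.4-19.0x).
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_males,n_females Cohort sizes.
#' @param chrom Chromosome name of the scan reference.
#' @param chrom_length Length of the scan reference in bp.
#' @param y_start 0-based start of the Y insertion on the scan reference.
#' @param y_length Y-insertion length in bp.
#' @param x_length X-specific segment length in bp (placed immediately after
#'   the Y insertion on the scan reference; 0 gives a pure-insertion
#'   architecture).
#' @param sex_linked_snps 1-based positions of fully sex-linked SNPs; must
#'   fall outside the Y and X segments (they are X/Y-shared sites where the Y
#'   carries a diagnostic allele).
#' @param n_autosomal_snps Number of autosomal HWE SNPs.
#' @param allele_freq_range Autosomal reference-allele frequencies are drawn
#'   uniformly from this range.
#' @param lambda Per-individual mean coverage (x-fold).
#' @param noise_mode `"poisson"` (per-base Poisson draws) or `"none"`
#'   (rounded expectations).
#' @param female_leak_rate Fraction of female per-individual coverage
#'   mismapping into the Y segment (default 0).
#' @param genotype_error_rate Probability a simulated genotype call is
#'   replaced by a random other class (default 0).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_males = 49L, n_females = 53L,
                       chrom = "LG11", chrom_length = 1000000L,
                       y_start = 500000L, y_length = 9149L,
                       x_length = 425L,
                       sex_linked_snps = NULL,
                       n_autosomal_snps = 10000L,
                       allele_freq_range = c(0.05, 0.95),
                       lambda = 15.0,
                       noise_mode = c("poisson", "none"),
                       female_leak_rate = 0,
                       genotype_error_rate = 0) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_males >= 1L, n_females >= 1L, chrom_length >= 1L,
            y_length >= 1L, x_length >= 0L, lambda > 0,
            female_leak_rate >= 0, genotype_error_rate >= 0,
            genotype_error_rate <= 1,
            y_start >= 0L, y_start + y_length + x_length <= chrom_length)
  y_end <- y_start + y_length            # 0-based half-open
  x_end <- y_end + x_length
  if (is.null(sex_linked_snps)) {
    # nine diagnostic sites flanking the insertion, span 14,950 bp (< 15 kb)
    up <- y_start + c(-4500L, -3200L, -2100L, -1300L, -400L)
    down <- x_end + c(226L, 426L, 676L, 876L)
    sex_linked_snps <- c(up, down)
  }
  sex_linked_snps <- sort(as.integer(sex_linked_snps))
  if (any(sex_linked_snps < 1L | sex_linked_snps > chrom_length))
    stop("sex-linked SNP positions outside the chromosome")
  in_seg <- sex_linked_snps > y_start & sex_linked_snps <= x_end
  if (any(in_seg))
    stop("sex-linked SNP positions must fall outside the Y/X segments")
  structure(list(seed = as.integer(seed), n_males = as.integer(n_males),
                 n_females = as.integer(n_females), chrom = chrom,
                 chrom_length = as.integer(chrom_length),
                 y_start = as.integer(y_start), y_length = as.integer(y_length),
                 x_length = as.integer(x_length),
                 sex_linked_snps = sex_linked_snps,
                 n_autosomal_snps = as.integer(n_autosomal_snps),
                 allele_freq_range = allele_freq_range, lambda = lambda,
                 noise_mode = noise_mode,
                 female_leak_rate = female_leak_rate,
                 genotype_error_rate = genotype_error_rate),
            class = "sim_config")
}

#' Ground truth of a simulated scenario
#'
#' @param config A [sim_config()].
#' @return List of class `ground_truth`: `y_interval` and `x_interval`
#'   (0-based half-open, on the scan-reference coordinates used by the depth
#'   tracks), `sex_linked_snps` (1-based), and the per-sample sexes.
#' @export
ground_truth <- function(config) {
  structure(list(
    chrom = config$chrom,
    y_interval = c(start = config$y_start,
                   end = config$y_start + config$y_length),
    x_interval = c(start = config$y_start + config$y_length,
                   end = config$y_start + config$y_length + config$x_length),
    sex_linked_snps = config$sex_linked_snps,
    samples = sim_cohort(config)[, c("sample", "sex")]),
    class = "ground_truth")
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sim_cohort <- function(config) {
  ids <- c(sprintf("m%03d", seq_len(config$n_males)),
           sprintf("f%03d", seq_len(config$n_females)))
  sex <- c(rep("male", config$n_males), rep("female", config$n_females))
  # per-sample coverages drawn once from the study's reported range
  set.seed(config$seed + 7L)
  cov <- round(stats::runif(length(ids), 12.4, 19.0), 1)
  sexed_cohort(ids, sex, cov)
}

#' Simulate the reference and the two sex haplotypes
#'
#' Generates a scan reference (hybrid chromosome: shared left flank, Y
#' insertion, X segment, shared right flank) plus the two pure haplotypes —
#' an X haplotype (flanks around the X segment) and a Y haplotype (the same
#' flanks around the Y insertion). The haplotype length difference equals
#' `y_length - x_length`.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (named `DNAStringSet`, the scan reference),
#'   `haplotypes` (`DNAStringSet` of `X_haplotype` and `Y_haplotype`) and
#'   `truth` ([ground_truth()]).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  left <- random_dna(config$y_start)
  y_seq <- random_dna(config$y_length)
  x_seq <- random_dna(config$x_length)
  right <- random_dna(config$chrom_length - config$y_start -
                        config$y_length - config$x_length)
  reference <- Biostrings::DNAStringSet(paste0(left, y_seq, x_seq, right))
  names(reference) <- config$chrom
  haplotypes <- Biostrings::DNAStringSet(c(
    X_haplotype = paste0(left, x_seq, right),
    Y_haplotype = paste0(left, y_seq, right)))
  list(reference = reference, haplotypes = haplotypes,
       truth = ground_truth(config))
}

#' Simulate cohort genotypes
#'
#' At each sex-linked position every male is heterozygous and every female
#' homozygous for one shared allele; each autosomal site draws its allele
#' frequency uniformly from `allele_freq_range` and genotypes per sample
#' under Hardy-Weinberg. `genotype_error_rate` independently replaces calls
#' with a random other class.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` ([sexed_cohort()]), `variants`
#'   ([variant_set()], sorted by position) and `truth`.
#' @export
simulate_genotypes <- function(config) {
  cohort <- sim_cohort(config)
  ns <- nrow(cohort)
  set.seed(config$seed + 1L)
  seg <- c(config$y_start + seq_len(config$y_length + config$x_length))
  allowed <- setdiff(seq_len(config$chrom_length),
                     c(seg, config$sex_linked_snps))
  auto_pos <- sort(sample(allowed, config$n_autosomal_snps))
  p <- stats::runif(config$n_autosomal_snps, config$allele_freq_range[1],
                    config$allele_freq_range[2])
  u <- matrix(stats::runif(config$n_autosomal_snps * ns),
              config$n_autosomal_snps, ns)
  p2 <- p^2
  het_cut <- p2 + 2 * p * (1 - p)
  auto_g <- matrix("hom_alt", config$n_autosomal_snps, ns)
  auto_g[u < het_cut] <- "het"
  auto_g[u < p2] <- "hom_ref"
  sl_g <- matrix(rep(ifelse(cohort$sex == "male", "het", "hom_ref"),
                     each = length(config$sex_linked_snps)),
                 length(config$sex_linked_snps), ns)
  pos <- c(config$sex_linked_snps, auto_pos)
  geno <- rbind(sl_g, auto_g)
  ord <- order(pos)
  pos <- pos[ord]
  geno <- geno[ord, , drop = FALSE]
  if (config$genotype_error_rate > 0) {
    flip <- which(matrix(stats::runif(length(geno)) <
                           config$genotype_error_rate, nrow(geno)))
    for (k in flip)
      geno[k] <- sample(setdiff(GT_CLASSES, geno[k]), 1L)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  colnames(geno) <- cohort$sample
  vs <- variant_set(chrom = rep(config$chrom, length(pos)), pos = pos,
                    ref = ref, alt = unname(alt), geno = geno)
  list(cohort = cohort, variants = vs, truth = ground_truth(config))
}

#' Simulate sex-pooled per-base depth tracks
#'
#' Expected pooled depth is `n * lambda` for a pool of `n` individuals over
#' shared sequence; inside the Y segment males drop to `n_m * lambda / 2`
#' (hemizygous) and females to `n_f * lambda * female_leak_rate`; inside the
#' X segment females stay at `n_f * lambda` (two X copies) while males drop
#' to `n_m * lambda / 2` (single X), giving the 2-fold female:male
#' per-individual signature. `noise_mode = "poisson"` draws each base
#' independently; `"none"` emits rounded expectations.
#'
#' @param config A [sim_config()].
#' @return List with `male` and `female` [depth_track()]s and `truth`.
#' @export
simulate_depth <- function(config) {
  L <- config$chrom_length
  tr <- ground_truth(config)
  yi <- (tr$y_interval["start"] + 1L):tr$y_interval["end"]
  xi <- if (config$x_length > 0L)
    (tr$x_interval["start"] + 1L):tr$x_interval["end"] else integer()
  exp_m <- rep(config$n_males * config$lambda, L)
  exp_m[yi] <- config$n_males * config$lambda / 2
  exp_m[xi] <- config$n_males * config$lambda / 2
  exp_f <- rep(config$n_females * config$lambda, L)
  exp_f[yi] <- config$n_females * config$lambda * config$female_leak_rate
  set.seed(config$seed + 2L)
  if (config$noise_mode == "poisson") {
    dm <- stats::rpois(L, exp_m)
    df <- stats::rpois(L, exp_f)
  } else {
    dm <- round(exp_m)
    df <- round(exp_f)
  }
  list(male = depth_track(config$chrom, dm, config$n_males, "male"),
       female = depth_track(config$chrom, df, config$n_females, "female"),
       truth = tr)
}

# one codon per amino acid (standard code), for deterministic reverse
# translation of designed proteins
AA_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_protein <- function(n) paste(sample(names(AA_CODON), n, replace = TRUE),
                                    collapse = "")

reverse_translate <- function(aa) {
  paste(AA_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

zk_motif_instance <- function() {
  x <- function(n) random_protein(n)
  paste0("C", x(2), "C", x(4), "H", x(4), "C")
}

#' Simulate gene copies, haplotype templates and a duplex primer set
#'
#' Builds a family of gene copies — functional copies whose translation
#' carries the zinc-knuckle motif, plus pseudogenized copies with an in-frame
#' premature stop or a single-base deletion — with their ground-truth labels
#' embedded in the FASTA-style names (`lesion=none|premature_stop|frameshift`,
#' `functional=TRUE|FALSE`). Also returns the two sex haplotypes from
#' [simulate_reference()] as PCR templates and a duplex primer set (common
#' forward + Y-specific forward + common reverse) with verified unique exact
#' sites.
#'
#' @param config A [sim_config()].
#' @param n_functional,n_premature_stop,n_frameshift Copy counts (defaults
#'   9, 2, 2: one Y copy plus eight functional autosomal copies, and four
#'   pseudogenized copies in total).
#' @return List with `cds` (named character vector), `labels` (data frame
#'   `copy_id`, `lesion`, `functional`), `templates` (`DNAStringSet`:
#'   `X_haplotype`, `Y_haplotype`), `primers` ([primer_set()]) and
#'   `expected_products` (data frame of the designed product lengths per
#'   haplotype).
#' @export
simulate_sequences_for_features <- function(config, n_functional = 9L,
                                            n_premature_stop = 2L,
                                            n_frameshift = 2L) {
  ref <- simulate_reference(config)
  set.seed(config$seed + 3L)
  make_cds <- function(n_pre = 30L, n_post = 30L) {
    aa <- paste0("M", random_protein(n_pre), zk_motif_instance(),
                 random_protein(n_post))
    paste0(reverse_translate(aa), "TAA")
  }
  copies <- character(0)
  labels <- list()
  add <- function(id, cds, lesion, functional) {
    copies[[id]] <<- cds
    labels[[length(labels) + 1L]] <<-
      data.frame(copy_id = id, lesion = lesion, functional = functional,
                 stringsAsFactors = FALSE)
  }
  # functional copies vary in length like the real family (143-633 aa)
  lens <- round(seq(143L, 633L, length.out = n_functional))
  for (i in seq_len(n_functional)) {
    n_extra <- max(0L, lens[i] - 16L)
    pre <- n_extra %/% 2L
    add(if (i == 1L) "zkY" else paste0("zk", i - 1L),
        make_cds(pre, n_extra - pre), "none", TRUE)
  }
  for (i in seq_len(n_premature_stop)) {
    cds <- make_cds()
    # in-frame stop before the motif
    cds <- paste0(substr(cds, 1L, 30L), "TAA", substr(cds, 31L, nchar(cds)))
    add(paste0("psi_stop", i), cds, "premature_stop", FALSE)
  }
  for (i in seq_len(n_frameshift)) {
    cds <- make_cds()
    # single-base deletion upstream of the motif
    cds <- paste0(substr(cds, 1L, 19L), substr(cds, 21L, nchar(cds)))
    add(paste0("psi_fs", i), cds, "frameshift", FALSE)
  }
  names(copies) <- vapply(labels, function(l)
    sprintf("%s lesion=%s functional=%s", l$copy_id, l$lesion, l$functional), "")
  primers <- design_duplex_primers(ref, config)
  list(cds = copies, labels = do.call(rbind, labels),
       templates = ref$haplotypes, primers = primers$primers,
       expected_products = primers$expected_products)
}

design_duplex_primers <- function(ref, config, primer_len = 20L) {
  hyb <- as.character(ref$reference[[1]])
  y0 <- config$y_start
  x_end <- y0 + config$y_length + config$x_length
  take <- function(start0) substr(hyb, start0 + 1L, start0 + primer_len)
  unique_site <- function(p) {
    all(vapply(as.character(ref$haplotypes), function(s)
      Biostrings::countPattern(p, Biostrings::DNAString(s)), 0L) <= 1L)
  }
  pick <- function(start0, shift_dir) {
    p <- take(start0)
    while (!unique_site(p)) {
      start0 <- start0 + shift_dir * primer_len
      p <- take(start0)
    }
    p
  }
  fc <- pick(y0 - 220L, -1L)
  fy <- pick(y0 + 100L, +1L)
  rc_site <- pick(x_end + 200L, +1L)
  rv <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rc_site)))
  primers <- primer_set(c("fwd_common", "fwd_y", "rev_common"),
                        c(fc, fy, rv),
                        c("forward_common", "forward_y", "reverse_common"))
  amp <- in_silico_pcr(ref$haplotypes, primers)
  list(primers = primers,
       expected_products = amp[, c("template_id", "forward_primer", "length")])
}

#' Write a complete synthetic fixture to disk
#'
#' Runs all generators for one configuration and writes: `reference.fa`,
#' `haplotypes.fa`, `cohort.tsv`, `cohort.vcf`, `male.depth.tsv`,
#' `female.depth.tsv`, `features.fa`, `templates.fa`, `primers.tsv` and
#' `truth.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
simulate_fixture <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  ref <- simulate_reference(config)
  gen <- simulate_genotypes(config)
  dep <- simulate_depth(config)
  feats <- simulate_sequences_for_features(config)
  Biostrings::writeXStringSet(ref$reference, fp("reference.fa"))
  Biostrings::writeXStringSet(ref$haplotypes, fp("haplotypes.fa"))
  write_sample_sheet(gen$cohort, fp("cohort.tsv"))
  write_vcf(gen$variants, fp("cohort.vcf"))
  write_depth_track(dep$male, fp("male.depth.tsv"))
  write_depth_track(dep$female, fp("female.depth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(feats$cds), fp("features.fa"))
  Biostrings::writeXStringSet(feats$templates, fp("templates.fa"))
  write_tsv(as.data.frame(feats$primers), fp("primers.tsv"))
  tr <- ref$truth
  jsonlite::write_json(list(chrom = tr$chrom,
                            y_interval = as.list(tr$y_interval),
                            x_interval = as.list(tr$x_interval),
                            sex_linked_snps = tr$sex_linked_snps),
                       fp("truth.json"), auto_unbox = TRUE)
  invisible(list(reference = fp("reference.fa"),
                 haplotypes = fp("haplotypes.fa"),
                 cohort = fp("cohort.tsv"), vcf = fp("cohort.vcf"),
                 male_depth = fp("male.depth.tsv"),
                 female_depth = fp("female.depth.tsv"),
                 features = fp("features.fa"), templates = fp("templates.fa"),
                 primers = fp("primers.tsv"), truth = fp("truth.json")))
}
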