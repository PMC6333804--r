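# Sex-linkage genotype filter: find variants heterozygous in all individuals
# of the heterogametic sex and homozygous in all of the other, then cluster
# passing variants into candidate regions.

#' Scan parameters for the sex-linkage genotype filter
#'
#' @param system Sex-determination system to call: `"XY"` (heterogametic
#'   males), `"ZW"` (heterogametic females) or `"both"`.
#' @param tolerance_het Allowed violations (non-het individuals) in the
#'   heterogametic sex; the strict filter uses 0.
#' @param tolerance_hom Allowed violations (non-hom individuals) in the
#'   homogametic sex.
#' @param missing_policy How a missing genotype counts: `"violation"`
#'   (default; a missing call cannot confirm linkage) or `"ignore"` (the
#'   sample is dropped from the site's counts).
#' @param require_same_hom_allele If `TRUE` (default), conforming homogametic
#'   individuals must all be homozygous for one identical allele (in an XY
#'   system the females share the X allele).
#' @param cluster_max_gap Maximum gap in bp between consecutive passing
#'   variants within one cluster.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(system = c("XY", "ZW", "both"),
                       tolerance_het = 0L, tolerance_hom = 0L,
                       missing_policy = c("violation", "ignore"),
                       require_same_hom_allele = TRUE,
                       cluster_max_gap = 50000L) {
  system <- match.arg(system)
  missing_policy <- match.arg(missing_policy)
  stopifnot(tolerance_het >= 0L, tolerance_hom >= 0L, cluster_max_gap >= 0L)
  structure(list(system = system,
                 tolerance_het = as.integer(tolerance_het),
                 tolerance_hom = as.integer(tolerance_hom),
                 missing_policy = missing_policy,
                 require_same_hom_allele = isTRUE(require_same_hom_allele),
                 cluster_max_gap = as.integer(cluster_max_gap)),
            class = "scan_params")
}

# Conformance counts for one orientation: het_sex must be het, hom_sex hom.
# Returns logical pass plus counts, vectorized over sites.
conformance <- function(geno, hom_allele, het_cols, hom_cols, params) {
  het_g <- geno[, het_cols, drop = FALSE]
  hom_g <- geno[, hom_cols, drop = FALSE]
  n_het_conf <- rowSums(het_g == "het")
  n_hom_conf <- rowSums(hom_g == "hom_ref" | hom_g == "hom_alt")
  n_miss_het <- rowSums(het_g == "missing")
  n_miss_hom <- rowSums(hom_g == "missing")
  eff_het <- length(het_cols) -
    if (params$missing_policy == "ignore") n_miss_het else 0L
  eff_hom <- length(hom_cols) -
    if (params$missing_policy == "ignore") n_miss_hom else 0L
  ok <- (eff_het - n_het_conf) <= params$tolerance_het &
        (eff_hom - n_hom_conf) <= params$tolerance_hom &
        eff_het > 0L & eff_hom > 0L
  if (params$require_same_hom_allele && any(ok)) {
    ha <- hom_allele[, hom_cols, drop = FALSE]
    n_all <- length(hom_cols)
    same <- vapply(which(ok), function(i) {
      a <- ha[i, ]
      a <- a[!is.na(a)]
      # conforming hom individuals must share one allele; with tolerance > 0
      # the modal allele's carriers are the conforming set
      if (!length(a)) return(params$tolerance_hom >= n_all)
      modal <- max(tabulate(a + 1L))
      eff <- n_all - if (params$missing_policy == "ignore")
        sum(geno[i, hom_cols] == "missing") else 0L
      (eff - modal) <= params$tolerance_hom
    }, logical(1))
    ok[ok] <- same
  }
  list(pass = ok, n_het_conforming = n_het_conf, n_hom_conforming = n_hom_conf,
       n_missing = n_miss_het + n_miss_hom)
}

#' Classify one or more variant sites by sex-linkage pattern
#'
#' Calls a site `XY` when (up to the tolerances) every male is heterozygous
#' and every female homozygous, `ZW` for the sex-swapped mirror, and `none`
#' otherwise. Missing genotypes are handled per `missing_policy`, and
#' `require_same_hom_allele` additionally demands that the conforming
#' homogametic individuals share one allele.
#'
#' @param vs A [variant_set()] covering all cohort samples.
#' @param cohort A [sexed_cohort()].
#' @param params A [scan_params()].
#' @return Data frame with one row per site: `chrom`, `pos`, `system_called`
#'   (`XY`/`ZW`/`none`), `n_het_conforming`, `n_hom_conforming`, `n_missing`.
#' @export
classify_variant <- function(vs, cohort, params = scan_params()) {
  absent <- setdiff(cohort$sample, vs$samples)
  if (length(absent))
    stop("site(s) do not cover cohort sample(s): ",
         paste(absent, collapse = ", "))
  males <- cohort$sample[cohort$sex == "male"]
  females <- cohort$sample[cohort$sex == "female"]
  if (params$tolerance_het >= min(length(males), length(females)) ||
      params$tolerance_hom >= min(length(males), length(females)))
    stop("tolerances must be smaller than the per-sex sample counts")
  n <- length(vs$pos)
  called <- rep("none", n)
  het_conf <- hom_conf <- miss <- integer(n)
  fill <- function(idx, cf) {
    het_conf[idx] <<- cf$n_het_conforming[idx]
    hom_conf[idx] <<- cf$n_hom_conforming[idx]
    miss[idx] <<- cf$n_missing[idx]
  }
  if (params$system %in% c("XY", "both")) {
    xy <- conformance(vs$geno, vs$hom_allele, males, females, params)
    called[xy$pass] <- "XY"
    fill(seq_len(n), xy)
  }
  if (params$system %in% c("ZW", "both")) {
    zw <- conformance(vs$geno, vs$hom_allele, females, males, params)
    take <- zw$pass & called == "none"
    called[take] <- "ZW"
    if (params$system == "ZW") fill(seq_len(n), zw) else fill(which(take), zw)
  }
  data.frame(chrom = vs$chrom, pos = vs$pos, system_called = called,
             n_het_conforming = het_conf, n_hom_conforming = hom_conf,
             n_missing = miss, stringsAsFactors = FALSE)
}

#' Scan a cohort for sex-linked variants and cluster them
#'
#' Applies [classify_variant()] to every site and groups passing sites, per
#' chromosome, into maximal clusters in which consecutive inter-variant gaps
#' do not exceed `params$cluster_max_gap`.
#'
#' @param vs A [variant_set()] sorted by (chrom, pos).
#' @param cohort A [sexed_cohort()].
#' @param params A [scan_params()].
#' @return List of class `sex_scan` with `variants` (passing sites, columns as
#'   [classify_variant()]) and `clusters` (one row per cluster: `chrom`,
#'   `start_pos`, `end_pos` (1-based, inclusive), `n_variants`, `span_bp` =
#'   `end_pos - start_pos + 1`, `system_called`).
#' @export
scan_sex_linked <- function(vs, cohort, params = scan_params()) {
  ord <- order(vs$chrom, vs$pos)
  if (is.unsorted(ord)) stop("variant set must be sorted by (chrom, pos)")
  pat <- classify_variant(vs, cohort, params)
  pass <- pat[pat$system_called != "none", , drop = FALSE]
  clusters <- cluster_positions(pass$chrom, pass$pos, pass$system_called,
                                params$cluster_max_gap)
  structure(list(variants = pass, clusters = clusters, params = params),
            class = "sex_scan")
}

cluster_positions <- function(chrom, pos, system_called, max_gap) {
  if (!length(pos))
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_variants = integer(),
                      span_bp = integer(), system_called = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(split(seq_along(pos), chrom), function(idx) {
    p <- pos[idx]
    new_cluster <- c(TRUE, diff(p) > max_gap)
    grp <- cumsum(new_cluster)
    do.call(rbind, lapply(split(seq_along(p), grp), function(j) {
      data.frame(chrom = chrom[idx[1L]], start_pos = min(p[j]),
                 end_pos = max(p[j]), n_variants = length(j),
                 span_bp = max(p[j]) - min(p[j]) + 1L,
                 system_called = paste(sort(unique(system_called[idx[j]])),
                                       collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start_pos), , drop = FALSE]
}

#' @export
print.sex_scan <- function(x, ...) {
  cat(sprintf("Sex-linkage scan: %d passing variant(s) in %d cluster(s)\n",
              nrow(x$variants), nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Monte-Carlo false-positive rate of the strict filter under HWE
#'
#' Estimates the fraction of autosomal Hardy-Weinberg sites (genotypes drawn
#' independently per sample at allele frequency `allele_freq`) that would pass
#' the strict sex-linkage filter, as a null calibration of the filter's
#' stringency for a given cohort size.
#'
#' @param n_m,n_f Numbers of males and females.
#' @param allele_freq Reference-allele frequency, strictly between 0 and 1.
#' @param n_sites Number of simulated sites.
#' @param seed Integer seed.
#' @param params A [scan_params()]; tolerances and `require_same_hom_allele`
#'   are honoured (missing genotypes are never drawn).
#' @return Fraction of sites passing, a number in \[0, 1\].
#' @export
false_positive_rate <- function(n_m, n_f, allele_freq, n_sites = 10000L,
                                seed = 1L, params = scan_params()) {
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("allele_freq must lie strictly between 0 and 1")
  p <- allele_freq
  q <- 1 - p
  set.seed(as.integer(seed))
  # count draws are equivalent in distribution to per-sample genotype draws
  het_m <- stats::rbinom(n_sites, n_m, 2 * p * q)
  f_hr <- stats::rbinom(n_sites, n_f, p^2)
  f_ha <- stats::rbinom(n_sites, n_f - f_hr, q^2 / (2 * p * q + q^2))
  males_ok <- (n_m - het_m) <= params$tolerance_het
  if (params$require_same_hom_allele) {
    females_ok <- (n_f - pmax(f_hr, f_ha)) <= params$tolerance_hom
  } else {
    females_ok <- (n_f - (f_hr + f_ha)) <= params$tolerance_hom
  }
  mean(males_ok & females_ok)
}
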