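# Combine SNP-pattern clusters and depth regions into ranked candidate
# sex-determining loci: concordant evidence (a sex-linked SNP cluster with
# hemizygous-depth regions inside its flanked interval) outranks either
# signal alone.

#' Integrate SNP clusters and depth regions into candidate loci
#'
#' For each sex-linked SNP cluster, depth regions overlapping the cluster
#' span extended by `flank` bp on both sides are attached; depth regions not
#' attached to any cluster become depth-only candidates. Candidates are
#' ranked by evidence count (SNP cluster + Y region + X region first), ties
#' broken by span descending, then by coordinate.
#'
#' @param clusters `clusters` data frame from [scan_sex_linked()] (columns
#'   `chrom`, `start_pos`, `end_pos`, 1-based inclusive).
#' @param regions `regions` data frame from [depth_scan()] (0-based
#'   half-open; refined bounds used when present).
#' @param flank Flanking distance in bp absorbed around each cluster
#'   (default 10000; absorbs window-resolution slack).
#' @return Data frame of class `candidate_loci`: `chrom`, `start`, `end`
#'   (0-based half-open, covering all members), `has_snp_cluster`,
#'   `has_Y_region`, `has_X_region`, `depth_regions_within_cluster_flanks`,
#'   `n_snp_variants`, `evidence_count`, `rank`.
#' @export
integrate_candidates <- function(clusters, regions, flank = 10000L) {
  need_cl <- c("chrom", "start_pos", "end_pos", "n_variants")
  if (!all(need_cl %in% names(clusters)))
    stop("clusters must have columns: ", paste(need_cl, collapse = ", "))
  need_rg <- c("chrom", "start", "end", "region_class")
  if (!all(need_rg %in% names(regions)))
    stop("regions must have columns: ", paste(need_rg, collapse = ", "))
  flank <- as.integer(flank)
  reg <- regions
  if (is.null(reg$refined_start)) {
    reg$use_start <- reg$start
    reg$use_end <- reg$end
  } else {
    reg$use_start <- ifelse(is.na(reg$refined_start), reg$start,
                            reg$refined_start)
    reg$use_end <- ifelse(is.na(reg$refined_end), reg$end, reg$refined_end)
  }
  used_region <- rep(FALSE, nrow(reg))
  cands <- list()
  for (i in seq_len(nrow(clusters))) {
    # cluster span in 0-based half-open coordinates
    c0 <- clusters$start_pos[i] - 1L
    c1 <- clusters$end_pos[i]
    lo <- max(0L, c0 - flank)
    hi <- c1 + flank
    hit <- which(reg$chrom == clusters$chrom[i] &
                   reg$use_start < hi & reg$use_end > lo)
    used_region[hit] <- TRUE
    has_y <- any(reg$region_class[hit] == "Y_specific")
    has_x <- any(reg$region_class[hit] == "X_like")
    member_bounds <- c(c0, c1, reg$use_start[hit], reg$use_end[hit])
    cands[[length(cands) + 1L]] <- data.frame(
      chrom = clusters$chrom[i],
      start = min(member_bounds), end = max(member_bounds),
      has_snp_cluster = TRUE, has_Y_region = has_y, has_X_region = has_x,
      depth_regions_within_cluster_flanks = length(hit) > 0L,
      n_snp_variants = clusters$n_variants[i],
      stringsAsFactors = FALSE)
  }
  for (j in which(!used_region)) {
    cands[[length(cands) + 1L]] <- data.frame(
      chrom = reg$chrom[j], start = reg$use_start[j], end = reg$use_end[j],
      has_snp_cluster = FALSE,
      has_Y_region = reg$region_class[j] == "Y_specific",
      has_X_region = reg$region_class[j] == "X_like",
      depth_regions_within_cluster_flanks = FALSE,
      n_snp_variants = 0L, stringsAsFactors = FALSE)
  }
  if (!length(cands)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      has_snp_cluster = logical(), has_Y_region = logical(),
                      has_X_region = logical(),
                      depth_regions_within_cluster_flanks = logical(),
                      n_snp_variants = integer(), evidence_count = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
    class(out) <- c("candidate_loci", "data.frame")
    return(out)
  }
  out <- do.call(rbind, cands)
  out$evidence_count <- out$has_snp_cluster + out$has_Y_region + out$has_X_region
  span <- out$end - out$start
  ord <- order(-out$evidence_count, -span, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_loci", "data.frame")
  out
}

#' @export
print.candidate_loci <- function(x, ...) {
  cat(sprintf("Candidate sex-determining loci: %d\n", nrow(x)))
  NextMethod()
}
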