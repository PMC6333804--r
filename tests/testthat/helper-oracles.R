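# Brute-force oracles and small scenario builders shared across tests.

# O(n^2) clustering oracle: connected components of the "within max_gap"
# graph on a line (equivalent to consecutive-gap chaining).
oracle_cluster <- function(pos, max_gap) {
  n <- length(pos)
  if (!n) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    while (length(frontier)) {
      comp[frontier] <- k
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                          is.na(comp))
    }
  }
  lapply(split(pos, comp), sort)
}

# Position-by-position window enumeration oracle.
oracle_windows <- function(L, window, step) {
  starts <- integer()
  s <- 0L
  while (s < L) {
    starts <- c(starts, s)
    s <- s + step
  }
  data.frame(start = starts, end = pmin(starts + window, L))
}

# Base-marking interval-union oracle (bridges gaps <= gap).
oracle_union <- function(starts, ends, gap) {
  if (!length(starts)) return(data.frame(start = integer(), end = integer()))
  hi <- max(ends) + gap + 1L
  cov <- logical(hi)
  for (i in seq_along(starts)) cov[(starts[i] + 1L):ends[i]] <- TRUE
  if (gap > 0L) {
    r <- rle(cov)
    off <- cumsum(r$lengths) - r$lengths
    for (j in which(!r$values & r$lengths <= gap)) {
      if (j > 1L && j < length(r$values))
        cov[(off[j] + 1L):(off[j] + r$lengths[j])] <- TRUE
    }
  }
  r <- rle(cov)
  ends2 <- cumsum(r$lengths)
  starts2 <- ends2 - r$lengths
  data.frame(start = starts2[r$values], end = ends2[r$values])
}

# Sliding-window motif oracle: explicit residue checks at the C/C/H/C
# offsets of the 14-mer.
oracle_motif <- function(aa) {
  aa <- toupper(aa)
  ch <- strsplit(aa, "")[[1]]
  hits <- integer()
  for (s in seq_len(max(0L, nchar(aa) - 13L))) {
    w <- ch[s:(s + 13L)]
    if (w[1] == "C" && w[4] == "C" && w[9] == "H" && w[14] == "C")
      hits <- c(hits, s)
  }
  hits
}

# A cohort/geno builder: matrix of classes with given male/female patterns.
build_variant <- function(n_m, n_f, male_class, female_class,
                          chrom = "c1", pos = 1L) {
  geno <- matrix(c(rep(male_class, length.out = n_m),
                   rep(female_class, length.out = n_f)), nrow = 1)
  colnames(geno) <- c(sprintf("m%02d", seq_len(n_m)),
                      sprintf("f%02d", seq_len(n_f)))
  variant_set(chrom, pos, "A", "C", geno)
}

toy_cohort <- function(n_m, n_f) {
  sexed_cohort(c(sprintf("m%02d", seq_len(n_m)), sprintf("f%02d", seq_len(n_f))),
               c(rep("male", n_m), rep("female", n_f)))
}

# Down-scaled scenario used by most simulator-backed tests.
small_cfg <- function(seed = 7L, noise_mode = "none", x_length = 400L, ...) {
  sim_config(seed = seed, n_males = 8L, n_females = 9L,
             chrom_length = 60000L, y_start = 30000L, y_length = 3000L,
             x_length = x_length, n_autosomal_snps = 300L,
             noise_mode = noise_mode, ...)
}

constant_track <- function(chrom, L, pooled, n, sex)
  depth_track(chrom, rep(pooled, L), n, sex)
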