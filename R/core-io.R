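# Shared domain containers and readers/writers for the standard formats the
# pipeline touches: sample sheet TSV, VCF 4.x, bedtools-genomecov "-d" depth
# tracks, BED and results TSV.
#
# Coordinate conventions: internal intervals and BED output are 0-based
# half-open; VCF and genomecov positions are 1-based and converted on read.

GT_CLASSES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a sexed cohort
#'
#' A sexed cohort is the unit of pooling and normalization: an ordered set of
#' samples, each labelled male or female, optionally with a per-sample mean
#' sequencing coverage (X-fold).
#'
#' @param sample Character vector of unique sample identifiers.
#' @param sex Character vector, one of `"male"`/`"female"` (or `"M"`/`"F"`,
#'   case-insensitive) per sample.
#' @param mean_coverage Optional numeric vector of per-sample mean coverage
#'   (X-fold, must be positive where not `NA`).
#' @return A `data.frame` of class `sexed_cohort` with columns `sample`,
#'   `sex`, `mean_coverage`.
#' @examples
#' sexed_cohort(c("s1", "s2"), c("M", "female"))
#' @export
sexed_cohort <- function(sample, sex, mean_coverage = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stop("duplicate sample id(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  sex <- normalize_sex(sex)
  if (length(sex) != length(sample))
    stop("'sample' and 'sex' must have equal length")
  if (sum(sex == "male") < 1L || sum(sex == "female") < 1L)
    stop("cohort needs at least 1 male and 1 female")
  if (is.null(mean_coverage)) mean_coverage <- rep(NA_real_, length(sample))
  mean_coverage <- as.numeric(mean_coverage)
  if (any(!is.na(mean_coverage) & mean_coverage <= 0))
    stop("mean_coverage must be > 0 where present")
  out <- data.frame(sample = sample, sex = sex, mean_coverage = mean_coverage,
                    stringsAsFactors = FALSE)
  class(out) <- c("sexed_cohort", "data.frame")
  out
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("m", "male")] <- "male"
  s[s %in% c("f", "female")] <- "female"
  bad <- setdiff(unique(s), c("male", "female"))
  if (length(bad))
    stop("unknown sex token(s): ", paste(bad, collapse = ", "))
  s
}

#' @export
print.sexed_cohort <- function(x, ...) {
  cat(sprintf("Sexed cohort: %d samples (%d males, %d females)\n",
              nrow(x), sum(x$sex == "male"), sum(x$sex == "female")))
  NextMethod()
}

#' Number of males / females in a cohort
#' @param cohort A [sexed_cohort()].
#' @return Integer count.
#' @export
n_males <- function(cohort) sum(cohort$sex == "male")

#' @rdname n_males
#' @export
n_females <- function(cohort) sum(cohort$sex == "female")

#' Read a sample sheet
#'
#' Reads a tab-separated sample sheet with header columns `sample`, `sex` and
#' optionally `mean_coverage`. Sex tokens `male`/`female` and the aliases
#' `M`/`F` are accepted case-insensitively.
#'
#' @param path Path to the TSV file.
#' @return A [sexed_cohort()] with samples in file order.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "sex") %in% names(df)))
    stop("sample sheet must have 'sample' and 'sex' columns")
  sexed_cohort(df$sample, df$sex,
               if ("mean_coverage" %in% names(df)) df$mean_coverage else NULL)
}

#' Write a sample sheet
#' @param cohort A [sexed_cohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(cohort, path) {
  df <- as.data.frame(cohort)
  if (all(is.na(df$mean_coverage))) df$mean_coverage <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify VCF genotype strings
#'
#' Maps GT strings to zygosity classes. `./.`, `.|.`, `.` and `NA` map to
#' `missing`; two identical called alleles to `hom_ref` (allele 0) or
#' `hom_alt`; two differing alleles to `het`. Phased (`|`) and unphased (`/`)
#' separators are treated identically, and any heterozygous combination counts
#' as `het` regardless of ALT index.
#'
#' @param gt Character vector of GT fields (a leading `GT` subfield is
#'   extracted if the string contains `:`).
#' @return A list with `class` (character, one of `hom_ref`, `het`, `hom_alt`,
#'   `missing`) and `hom_allele` (integer allele index for homozygous calls,
#'   otherwise `NA`).
#' @export
genotype_class <- function(gt) {
  gt <- sub(":.*$", "", as.character(gt))
  cls <- rep(NA_character_, length(gt))
  hom <- rep(NA_integer_, length(gt))
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  cls[miss] <- "missing"
  todo <- which(!miss)
  if (length(todo)) {
    g <- gt[todo]
    ok <- grepl("^[0-9.]+[/|][0-9.]+$", g)
    if (any(!ok))
      stop("malformed GT field(s): ", paste(unique(g[!ok]), collapse = ", "))
    a1 <- sub("^([0-9.]+)[/|].*$", "\\1", g)
    a2 <- sub("^[0-9.]+[/|]([0-9.]+)$", "\\1", g)
    part_miss <- a1 == "." | a2 == "."
    cls[todo[part_miss]] <- "missing"
    det <- !part_miss
    i1 <- suppressWarnings(as.integer(a1[det]))
    i2 <- suppressWarnings(as.integer(a2[det]))
    k <- todo[det]
    cls[k] <- ifelse(i1 != i2, "het", ifelse(i1 == 0L, "hom_ref", "hom_alt"))
    hom[k] <- ifelse(i1 == i2, i1, NA_integer_)
  }
  list(class = cls, hom_allele = hom)
}

#' Read cohort genotypes from a VCF
#'
#' Reads a (plain or bgzipped) VCF whose sample columns are a superset of the
#' cohort's samples and derives per-sample genotype classes from the GT field.
#'
#' @param path Path to the VCF file.
#' @param cohort A [sexed_cohort()]; its samples must all be present in the
#'   VCF header.
#' @return A `variant_set`: list with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `geno` (sites x samples character matrix of genotype classes),
#'   `hom_allele` (matching integer matrix of homozygous allele indices) and
#'   `samples`.
#' @export
read_vcf <- function(path, cohort) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  absent <- setdiff(cohort$sample, colnames(gt))
  if (length(absent))
    stop("cohort sample(s) absent from VCF header: ",
         paste(absent, collapse = ", "))
  gt <- gt[, cohort$sample, drop = FALSE]
  gc <- genotype_class(as.vector(gt))
  n <- nrow(gt)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variant_set(chrom = as.character(fix[, "CHROM"]),
              pos = as.integer(fix[, "POS"]),
              ref = as.character(fix[, "REF"]),
              alt = as.character(fix[, "ALT"]),
              geno = matrix(gc$class, nrow = n,
                            dimnames = list(NULL, cohort$sample)),
              hom_allele = matrix(gc$hom_allele, nrow = n,
                                  dimnames = list(NULL, cohort$sample)))
}

#' Construct a variant set
#'
#' Container for per-site genotype classes across a cohort (the input to the
#' sex-linkage scan). Usually produced by [read_vcf()] or
#' [simulate_genotypes()].
#'
#' @param chrom,pos,ref,alt Per-site fields (`pos` 1-based, VCF convention).
#' @param geno Sites x samples character matrix over
#'   `hom_ref`/`het`/`hom_alt`/`missing`, with sample column names.
#' @param hom_allele Optional matching integer matrix of allele indices for
#'   homozygous calls (`NA` elsewhere); derived as all-`NA` if omitted.
#' @return A list of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, geno, hom_allele = NULL) {
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("pos must be >= 1")
  if (length(chrom) != nrow(geno)) stop("chrom/geno dimension mismatch")
  bad <- setdiff(unique(as.vector(geno)), GT_CLASSES)
  if (length(bad)) stop("unknown genotype class: ", paste(bad, collapse = ", "))
  if (is.null(hom_allele)) {
    # biallelic assumption for derived allele indices
    hom_allele <- matrix(NA_integer_, nrow(geno), ncol(geno),
                         dimnames = dimnames(geno))
    hom_allele[geno == "hom_ref"] <- 0L
    hom_allele[geno == "hom_alt"] <- 1L
  }
  structure(list(chrom = as.character(chrom), pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, hom_allele = hom_allele,
                 samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("Variant set: %d sites x %d samples on %d chromosome(s)\n",
              length(x$pos), length(x$samples), length(unique(x$chrom))))
  invisible(x)
}

#' @export
length.variant_set <- function(x) length(x$pos)

#' Write a variant set as VCF
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; genotype classes are
#' rendered as `0/0`, `0/1`, `1/1` or `./.` (for `hom_alt` the stored
#' homozygous allele index is used when available).
#'
#' @param vs A [variant_set()].
#' @param path Output path (plain `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  gt <- matrix("./.", nrow = length(vs$pos), ncol = length(vs$samples))
  gt[vs$geno == "hom_ref"] <- "0/0"
  gt[vs$geno == "het"] <- "0/1"
  ha <- vs$hom_allele
  ha[is.na(ha)] <- 1L
  idx <- vs$geno == "hom_alt"
  gt[idx] <- paste0(ha[idx], "/", ha[idx])
  header <- c("##fileformat=VCFv4.2",
              "##source=sexscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", vs$samples), collapse = "\t"))
  body <- paste(vs$chrom, vs$pos, ".", vs$ref, vs$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a depth track
#'
#' A dense per-base read-depth array for one chromosome and one sex pool
#' (summed over all individuals of that sex). Internal indexing is 0-based:
#' `depth[i]` is the pooled depth at 0-based position `i - 1`.
#'
#' @param chrom Chromosome name.
#' @param depth Non-negative numeric vector, one entry per base.
#' @param n_individuals Pool size (number of individuals summed).
#' @param sex `"male"` or `"female"`.
#' @return A list of class `depth_track`.
#' @export
depth_track <- function(chrom, depth, n_individuals, sex) {
  if (any(depth < 0)) stop("depth must be non-negative")
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  structure(list(chrom = as.character(chrom), depth = as.numeric(depth),
                 n_individuals = as.integer(n_individuals),
                 sex = normalize_sex(sex)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("Depth track: %s, %d bp, %s pool of %d (mean pooled depth %.2f)\n",
              x$chrom, length(x$depth), x$sex, x$n_individuals,
              mean(x$depth)))
  invisible(x)
}

#' Read per-base depth tracks (bedtools genomecov -d dialect)
#'
#' Reads rows of `(chrom, 1-based position, depth)` — the per-position output
#' of `bedtools genomecov -d` — into dense per-base arrays. Positions absent
#' from the file are filled with depth 0.
#'
#' @param path Path to the (headerless) TSV.
#' @param chrom_lengths Named integer vector mapping chromosome name to length
#'   in bp.
#' @param sex `"male"` or `"female"` — which sex pool the track summarizes.
#' @param n_individuals Pool size.
#' @return Named list of [depth_track()] objects, one per chromosome in
#'   `chrom_lengths`.
#' @export
read_depth_track <- function(path, chrom_lengths, sex, n_individuals) {
  if (any(chrom_lengths < 1L)) stop("chromosome lengths must be >= 1")
  empty <- file.size(path) == 0
  dt <- if (empty) data.table::data.table(chrom = character(),
                                          pos = integer(), depth = numeric())
        else data.table::fread(path, header = FALSE, sep = "\t",
                               col.names = c("chrom", "pos", "depth"))
  if (nrow(dt)) {
    if (any(dt$depth < 0)) stop("negative depth in ", path)
    unknown <- setdiff(unique(dt$chrom), names(chrom_lengths))
    if (length(unknown))
      stop("chromosome(s) not in layout: ", paste(unknown, collapse = ", "))
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    d <- numeric(L)
    sub <- dt[dt$chrom == ch, ]
    if (nrow(sub)) {
      if (any(sub$pos < 1L | sub$pos > L))
        stop("position outside chromosome ", ch, " (length ", L, ")")
      d[sub$pos] <- sub$depth
    }
    depth_track(ch, d, n_individuals, sex)
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Write per-base depth tracks (bedtools genomecov -d dialect)
#'
#' @param tracks A [depth_track()] or list of them.
#' @param path Output TSV path (chrom, 1-based position, depth; no header).
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(tracks, path) {
  if (inherits(tracks, "depth_track")) tracks <- list(tracks)
  tabs <- lapply(tracks, function(tr)
    data.table::data.table(chrom = tr$chrom,
                           pos = seq_along(tr$depth),
                           depth = tr$depth))
  data.table::fwrite(data.table::rbindlist(tabs), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

check_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start < 0 | df$start >= df$end))
    stop("interval invariant violated: need 0 <= start < end")
  invisible(df)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open, tab-separated BED with no header. Columns beyond
#' `chrom`, `start`, `end` (e.g. a name or score) are appended in order.
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optional
#'   annotation columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  check_intervals(df)
  keep <- c("chrom", "start", "end", setdiff(names(df), c("chrom", "start", "end")))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write records as TSV (with header)
#' @param df Data frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
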