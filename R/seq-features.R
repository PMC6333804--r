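# Sequence-level characterization of candidate genes: CCHC zinc-knuckle
# motif scan, functional-vs-pseudogene copy classification, and the duplex
# in-silico PCR sex test (one band in females, two in males).

ZK_REGEX <- "(?=C.{2}C.{4}H.{4}C)"
ZK_LEN <- 14L
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Scan a protein for the zinc-knuckle motif
#'
#' Finds all (possibly overlapping) 14-residue windows matching the
#' zinc-knuckle consensus Cys-X2-Cys-X4-His-X4-Cys (X = any amino acid),
#' the metal-binding motif of retroviral nucleocapsid-like RNA-binding
#' proteins. Matching is case-insensitive and proceeds left to right.
#'
#' @param protein Character vector of amino-acid sequences (20-letter
#'   alphabet plus `X` and `*`), optionally named.
#' @return Data frame with one row per hit: `sequence_id`, `start`, `end`
#'   (1-based inclusive residue coordinates), `matched` (the 14-mer).
#' @examples
#' find_zinc_knuckle("CAACAAAAHAAAAC")
#' @export
find_zinc_knuckle <- function(protein) {
  ids <- names(protein)
  protein <- as.character(protein)
  if (is.null(ids)) ids <- paste0("seq", seq_along(protein))
  hits <- lapply(seq_along(protein), function(i) {
    s <- toupper(protein[[i]])
    bad <- setdiff(unique(strsplit(s, "")[[1]]), AA_ALPHABET)
    if (length(bad))
      stop("illegal residue(s) in ", ids[i], ": ", paste(bad, collapse = ", "))
    m <- gregexpr(ZK_REGEX, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    data.frame(sequence_id = ids[i], start = starts,
               end = starts + ZK_LEN - 1L,
               matched = substring(s, starts, starts + ZK_LEN - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a gene copy as functional or pseudogenized
#'
#' Translates the CDS in frame 0 with the standard nuclear code and flags the
#' lesions that pseudogenize a copy: a premature stop codon (a stop before
#' the final codon) or a frameshift (CDS length not a multiple of 3, as left
#' by a single-base indel). The zinc-knuckle motif is searched in the
#' translation up to the first stop. A copy is functional iff it has the
#' motif and neither lesion.
#'
#' @param cds Character vector of nucleotide coding sequences (annotated
#'   frame starts at base 1), optionally named.
#' @return Data frame with one row per copy: `copy_id`, `has_motif`,
#'   `premature_stop`, `first_stop_codon` (codon index of the first stop, or
#'   `NA`), `frameshift_flag`, `functional`.
#' @export
classify_copy <- function(cds) {
  ids <- names(cds)
  cds <- as.character(cds)
  if (any(!nzchar(cds))) stop("empty sequence")
  if (is.null(ids)) ids <- paste0("copy", seq_along(cds))
  rows <- lapply(seq_along(cds), function(i) {
    s <- toupper(cds[[i]])
    frameshift <- (nchar(s) %% 3L) != 0L
    n_codon <- nchar(s) %/% 3L
    aa <- if (n_codon > 0L) {
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, 1L, n_codon * 3L)),
        if.fuzzy.codon = "X"))
    } else ""
    stops <- which(strsplit(aa, "")[[1]] == "*")
    first_stop <- if (length(stops)) stops[1L] else NA_integer_
    premature <- length(stops) > 0L && stops[1L] < n_codon
    upto <- if (length(stops)) substr(aa, 1L, stops[1L] - 1L) else aa
    has_motif <- nzchar(upto) && nrow(find_zinc_knuckle(upto)) > 0L
    data.frame(copy_id = ids[i], has_motif = has_motif,
               premature_stop = premature, first_stop_codon = first_stop,
               frameshift_flag = frameshift,
               functional = has_motif && !premature && !frameshift,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a duplex primer set
#'
#' The diagnostic design uses two forward primers — one Y-specific and one
#' matching a common sequence upstream of the X and Y regions — sharing a
#' common reverse primer downstream, so that PCR yields a single band in
#' females and a double band in males.
#'
#' @param name Character vector of primer names.
#' @param sequence DNA sequences over `A`/`C`/`G`/`T`, length >= 15.
#' @param role One of `forward_common`, `forward_y`, `reverse_common` per
#'   primer.
#' @return Data frame of class `primer_set`.
#' @export
primer_set <- function(name, sequence, role) {
  sequence <- toupper(as.character(sequence))
  if (any(grepl("[^ACGT]", sequence)))
    stop("primer sequences must be over A/C/G/T")
  if (any(nchar(sequence) < 15L)) stop("primers must be >= 15 bp")
  role <- match.arg(role, c("forward_common", "forward_y", "reverse_common"),
                    several.ok = TRUE)
  out <- data.frame(name = as.character(name), sequence = sequence,
                    role = role, stringsAsFactors = FALSE)
  class(out) <- c("primer_set", "data.frame")
  out
}

#' Read a primer set from TSV
#' @param path TSV with header columns `name`, `sequence`, `role`.
#' @return A [primer_set()].
#' @export
read_primer_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  primer_set(df$name, df$sequence, df$role)
}

# All match start positions of `pattern` in `subject` with at most
# `max_mismatch` mismatches and an exact base at `anchor` ("last" = the
# pattern's 3' base for a plus-strand primer, "first" = the base that is the
# primer 3' end after reverse complementing).
primer_sites <- function(pattern, subject, max_mismatch, anchor) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mismatch)
  st <- BiocGenerics::start(m)
  if (!length(st)) return(integer())
  if (max_mismatch > 0L) {
    keep <- vapply(seq_along(st), function(i) {
      s <- as.character(m[[i]])
      if (anchor == "last") substring(s, nchar(s), nchar(s)) ==
        substring(pattern, nchar(pattern), nchar(pattern))
      else substring(s, 1L, 1L) == substring(pattern, 1L, 1L)
    }, logical(1))
    st <- st[keep]
  }
  st
}

#' In-silico PCR over template sequences
#'
#' For every ordered pair (forward-primer site on the plus strand, downstream
#' site whose sequence is the reverse complement of a reverse primer), an
#' amplicon is emitted if the product is at most `max_product` bp and each
#' primer matches with at most `max_mismatch` mismatches; the 3'-terminal
#' base of each primer must match exactly. Mismatch counting is plain
#' Hamming — no thermodynamics.
#'
#' @param templates Named character vector or `Biostrings::DNAStringSet` of
#'   template sequences.
#' @param primers A [primer_set()].
#' @param max_product Maximum product length in bp (default 20000, enough for
#'   long-range products spanning a ~9 kb Y insertion).
#' @param max_mismatch Maximum mismatches per primer (default 0).
#' @return Data frame with one row per amplicon: `template_id`,
#'   `forward_primer`, `reverse_primer`, `start`, `end` (1-based inclusive on
#'   the template), `length`.
#' @export
in_silico_pcr <- function(templates, primers, max_product = 20000L,
                          max_mismatch = 0L) {
  if (!inherits(templates, "DNAStringSet")) {
    nms <- names(templates)
    templates <- Biostrings::DNAStringSet(toupper(unlist(templates)))
    names(templates) <- nms
  }
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))
  fwd <- primers[primers$role %in% c("forward_common", "forward_y"), ,
                 drop = FALSE]
  rev <- primers[primers$role == "reverse_common", , drop = FALSE]
  out <- list()
  for (t in seq_along(templates)) {
    subj <- templates[[t]]
    for (i in seq_len(nrow(fwd))) {
      fs <- primer_sites(fwd$sequence[i], subj, max_mismatch, "last")
      if (!length(fs)) next
      f_len <- nchar(fwd$sequence[i])
      for (j in seq_len(nrow(rev))) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(rev$sequence[j])))
        rs <- primer_sites(rc, subj, max_mismatch, "first")
        if (!length(rs)) next
        r_len <- nchar(rc)
        for (a in fs) for (b in rs) {
          if (b <= a + f_len - 1L) next        # reverse site strictly downstream
          len <- b + r_len - 1L - a + 1L
          if (len > max_product) next
          out[[length(out) + 1L]] <- data.frame(
            template_id = ids[t], forward_primer = fwd$name[i],
            reverse_primer = rev$name[j], start = a, end = b + r_len - 1L,
            length = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(template_id = character(), forward_primer = character(),
                      reverse_primer = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call sex from duplex PCR amplicons
#'
#' Applies the duplex band logic to the amplicons predicted on one
#' individual's haplotype sequences (two X haplotypes for a female; one X and
#' one Y for a male): `male` iff both the Y-specific product
#' (forward_y x reverse_common) and the common product
#' (forward_common x reverse_common) are present, `female` iff only the
#' common product, `inconclusive` otherwise.
#'
#' @param amplicons Output of [in_silico_pcr()] run on the individual's
#'   template set.
#' @param primers The [primer_set()] used.
#' @return List of class `sex_test_result` with `call` and the supporting
#'   `amplicons`.
#' @export
sex_call <- function(amplicons, primers) {
  y_name <- primers$name[primers$role == "forward_y"]
  c_name <- primers$name[primers$role == "forward_common"]
  has_y <- any(amplicons$forward_primer %in% y_name)
  has_common <- any(amplicons$forward_primer %in% c_name)
  call <- if (has_y && has_common) "male"
          else if (has_common) "female"
          else "inconclusive"
  structure(list(call = call, amplicons = amplicons), class = "sex_test_result")
}

#' @export
print.sex_test_result <- function(x, ...) {
  cat(sprintf("Sex-test call: %s (%d product(s): %s)\n", x$call,
              nrow(x$amplicons),
              paste(x$amplicons$length, collapse = ", ")))
  invisible(x)
}

#' Duplex PCR sex test across individuals
#'
#' Convenience wrapper: runs [in_silico_pcr()] on each individual's haplotype
#' set and calls sex per individual.
#'
#' @param haplotypes_by_individual Named list; each element a named character
#'   vector (or `DNAStringSet`) of that individual's haplotype sequences.
#' @param primers A [primer_set()].
#' @param ... Passed to [in_silico_pcr()].
#' @return Data frame `individual`, `call`, `n_products`.
#' @export
pcr_sex_test <- function(haplotypes_by_individual, primers, ...) {
  rows <- lapply(names(haplotypes_by_individual), function(id) {
    amp <- in_silico_pcr(haplotypes_by_individual[[id]], primers, ...)
    # a product is a band: same-length duplicates across the two haplotypes
    # collapse on a gel
    data.frame(individual = id, call = sex_call(amp, primers)$call,
               n_products = length(unique(amp$length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
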