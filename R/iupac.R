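# IUPAC nucleotide alphabet: code -> set of plain bases, sourced from
# Biostrings so the degeneracy table has a single canonical origin.
.iupac_sets <- local({
  codes <- Biostrings::IUPAC_CODE_MAP
  codes <- codes[names(codes) %in%
                   c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N")]
  lapply(strsplit(codes, ""), identity)
})

.iupac_alphabet <- names(.iupac_sets)

# 15 x 15 logical matrix: TRUE iff the two codes' base sets intersect.
.iupac_compat <- local({
  codes <- names(.iupac_sets)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(.iupac_sets[[a]], .iupac_sets[[b]])) > 0L
  }
  m
})

#' Validate and normalize a DNA sequence
#'
#' Uppercases the input and checks every residue against the 15-letter IUPAC
#' DNA alphabet (`A C G T R Y S W K M B D H V N`). `U` is rejected: the
#' package models DNA templates and oligos only.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages (e.g. an accession).
#' @return The uppercased sequences, invisibly unchanged otherwise.
#' @examples
#' validate_dna("acgtRYn")
#' @export
validate_dna <- function(x, what = NULL) {
  stopifnot(is.character(x))
  if (any(is.na(x)) || any(!nzchar(x))) {
    stop("sequences must be non-empty and non-NA", call. = FALSE)
  }
  x <- toupper(x)
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% .iupac_alphabet)
    if (length(bad)) {
      lab <- if (is.null(what)) {
        if (length(x) > 1L) paste0("sequence ", i) else "sequence"
      } else {
        what[[min(i, length(what))]]
      }
      stop(sprintf("illegal residue '%s' at position %d in %s",
                   chars[bad[1]], bad[1], lab), call. = FALSE)
    }
  }
  x
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement (delegates to Biostrings).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' dna_revcomp("AARGT")  # "ACYTT"
#' @export
dna_revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of a sequence
#'
#' Fraction of residues that are `G`, `C` or `S` (the G/C degenerate code);
#' other degenerate codes do not count towards GC.
#'
#' @param x Character vector of DNA sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  if (!length(x)) return(numeric(0))
  n <- nchar(x)
  gc <- vapply(strsplit(toupper(x), "", fixed = TRUE),
               function(ch) sum(ch %in% c("G", "C", "S")), integer(1))
  ifelse(n > 0L, gc / n, NA_real_)
}

#' Compatibility of two IUPAC codes
#'
#' Two codes are compatible iff their nucleotide sets intersect, so a
#' degenerate template base (`N`, `R`, ...) never scores as a mismatch when
#' it could represent the primer base. Vectorized; recycles like arithmetic.
#'
#' @param pattern_base,template_base IUPAC codes (single characters).
#' @return Logical vector.
#' @examples
#' iupac_compatible("R", "G")  # TRUE: R = {A,G}
#' iupac_compatible("C", "T")  # FALSE
#' iupac_compatible("N", "K")  # TRUE: N matches anything
#' @export
iupac_compatible <- function(pattern_base, template_base) {
  p <- toupper(pattern_base)
  t <- toupper(template_base)
  if (any(!p %in% .iupac_alphabet) || any(!t %in% .iupac_alphabet)) {
    stop("arguments must be single IUPAC DNA codes", call. = FALSE)
  }
  .iupac_compat[cbind(p, t)]
}
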