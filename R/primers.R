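#' Construct a primer
#'
#' An oligo written 5'→3' on its own strand, at least 8 nt, IUPAC degenerate
#' codes allowed.
#'
#' @param name Primer name.
#' @param seq Primer sequence (IUPAC string).
#' @return A `primer` object.
#' @export
primer <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- validate_dna(seq, what = name)
  if (nchar(seq) < 8L) {
    stop("primer '", name, "' is shorter than 8 nt", call. = FALSE)
  }
  structure(list(name = name, seq = seq), class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3'  (%d nt)\n", x$name, x$seq, nchar(x$seq)))
  invisible(x)
}

#' Construct a primer pair
#'
#' @param forward,reverse [primer()] objects, each written 5'→3' on its own
#'   strand; names must differ.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward, reverse) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (identical(forward$name, reverse$name)) {
    stop("forward and reverse primers must have distinct names", call. = FALSE)
  }
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  print(x$forward); print(x$reverse)
  invisible(x)
}

#' The default D2 mosquito metabarcoding primer pair
#'
#' The universal-Culicidae pair targeting the D2 expansion segment of the 28S
#' rRNA gene. The forward primer ends in a 3'-cytosine that is nearly
#' universal within Culicidae and rare elsewhere, which is what restricts
#' amplification to mosquitoes under the 3'-anchor criterion; the reverse
#' priming site is conserved across essentially all arthropods.
#'
#' @return A [primer_pair()].
#' @export
mozzie_d2_primers <- function() {
  primer_pair(
    primer("Mozzie.D2.Uni.F", "AAGCACTCTGAATAGAGAGTC"),
    primer("Mozzie.D2.Uni.R", "TGGTCCGTGTTTCAAGAC")
  )
}

#' Matching policy for in-silico PCR
#'
#' @param max_mismatches Mismatch budget per primer (default 5, the
#'   conventional tolerance for binding-site surveys). The 3'-terminal
#'   position counts towards this budget as well as driving the 3' criterion.
#' @param require_three_prime If `TRUE` (default) a site whose 3'-terminal
#'   primer base is incompatible with the template cannot seed an amplicon:
#'   polymerase extension is assumed blocked by a 3' mismatch. Sites are
#'   still reported, flagged, by [find_binding_sites()]; exclusion happens in
#'   [amplify()].
#' @param max_amplicon_length Longest primer-inclusive product considered
#'   (default 2000 nt, a practical cap; must exceed the summed primer
#'   lengths).
#' @return A `match_policy` object.
#' @export
match_policy <- function(max_mismatches = 5L, require_three_prime = TRUE,
                         max_amplicon_length = 2000L) {
  stopifnot(max_mismatches >= 0L, is.logical(require_three_prime),
            max_amplicon_length > 0L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 require_three_prime = isTRUE(require_three_prime),
                 max_amplicon_length = as.integer(max_amplicon_length)),
            class = "match_policy")
}
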