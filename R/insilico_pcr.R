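# In-silico PCR engine. Coordinates are 0-based half-open intervals on the
# forward strand throughout (a site [s, e) covers forward-strand residues
# s+1 .. e in R's 1-based substring terms); 1-based labels appear only in
# documentation prose.

#' Score a primer against an equal-length template window
#'
#' Counts positions where the primer base is incompatible with the template
#' base (IUPAC set intersection empty) and reports whether the 3'-most primer
#' base is compatible with its template base. A 3' mismatch is one event with
#' two consequences: it increments the mismatch count *and* clears
#' `three_prime_match`.
#'
#' @param primer A [primer()].
#' @param window Template window(s), same length as the primer, written in
#'   primer orientation. Vectorized over windows.
#' @return A tibble with one row per window: `mismatches`,
#'   `three_prime_match`.
#' @export
score_site <- function(primer, window) {
  stopifnot(inherits(primer, "primer"))
  window <- validate_dna(window)
  m <- nchar(primer$seq)
  if (any(nchar(window) != m)) {
    stop("window length must equal primer length (", m, ")", call. = FALSE)
  }
  p <- strsplit(primer$seq, "", fixed = TRUE)[[1]]
  wm <- matrix(unlist(strsplit(window, "", fixed = TRUE)),
               nrow = length(window), byrow = TRUE)
  mm <- integer(length(window))
  for (j in seq_len(m)) {
    mm <- mm + !.iupac_compat[cbind(rep(p[j], length(window)), wm[, j])]
  }
  tibble(mismatches = mm,
         three_prime_match = .iupac_compat[cbind(rep(p[m], length(window)),
                                                 wm[, m])])
}

# Scan one template (character scalar) with one primer; both strands.
# Returns start/end on the forward strand; site_seq in primer orientation.
.scan_template <- function(primer, template, max_mismatches) {
  m <- nchar(primer$seq)
  n <- nchar(template)
  empty <- tibble(strand = character(0), start = integer(0),
                  end = integer(0), mismatches = integer(0),
                  three_prime_match = logical(0), site_seq = character(0))
  if (n < m) return(empty)
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  nw <- n - m + 1L
  scan_one <- function(pat_chars, three_prime_col) {
    mm <- integer(nw)
    for (j in seq_len(m)) {
      mm <- mm + !.iupac_compat[cbind(rep(pat_chars[j], nw),
                                      tch[j:(nw + j - 1L)])]
    }
    tp <- .iupac_compat[cbind(rep(pat_chars[three_prime_col], nw),
                              tch[three_prime_col:(nw + three_prime_col - 1L)])]
    keep <- which(mm <= max_mismatches)
    list(start = keep - 1L, mm = mm[keep], tp = tp[keep])
  }
  p_fwd <- strsplit(primer$seq, "", fixed = TRUE)[[1]]
  # "-" strand: the primer binds the reverse strand; equivalently its reverse
  # complement, read 5'->3' on the forward strand, matches the window. The
  # primer's 3'-terminal base then sits at the window's *first* position
  # (complementation preserves IUPAC compatibility, so scoring the revcomp
  # pattern against the forward strand is exact).
  p_rev <- strsplit(dna_revcomp(primer$seq), "", fixed = TRUE)[[1]]
  plus <- scan_one(p_fwd, m)
  minus <- scan_one(p_rev, 1L)
  res <- list()
  if (length(plus$start)) {
    res$plus <- tibble(strand = "+", start = plus$start,
                       end = plus$start + m, mismatches = plus$mm,
                       three_prime_match = plus$tp,
                       site_seq = substring(template, plus$start + 1L,
                                            plus$start + m))
  }
  if (length(minus$start)) {
    res$minus <- tibble(strand = "-", start = minus$start,
                        end = minus$start + m, mismatches = minus$mm,
                        three_prime_match = minus$tp,
                        site_seq = dna_revcomp(
                          substring(template, minus$start + 1L,
                                    minus$start + m)))
  }
  if (!length(res)) empty else bind_rows(res)
}

#' Locate candidate primer binding sites
#'
#' Scans every window of every entry, on both strands, and reports all sites
#' within the mismatch budget. Sites failing the 3' criterion are *retained*
#' and flagged (`three_prime_match = FALSE`); [amplify()] applies the
#' exclusion. Coordinates are 0-based half-open on the forward strand;
#' `site_seq` is the template window in primer orientation (reverse
#' complemented for `-` strand sites), which is what binding-site logos
#' summarise.
#'
#' @param primer A [primer()].
#' @param refs Reference-set tibble (one or more entries).
#' @param policy A [match_policy()].
#' @return A tibble: `accession`, `primer`, `strand`, `start`, `end`,
#'   `mismatches`, `three_prime_match`, `site_seq`.
#' @export
find_binding_sites <- function(primer, refs, policy = match_policy()) {
  stopifnot(inherits(primer, "primer"), inherits(policy, "match_policy"))
  purrr::map2(refs$accession, refs$seq, function(acc, s) {
    hits <- .scan_template(primer, s, policy$max_mismatches)
    if (nrow(hits)) mutate(hits, accession = acc, primer = primer$name)
    else NULL
  }) |>
    purrr::compact() |>
    bind_rows() |>
    (\(x) if (nrow(x)) select(x, "accession", "primer", "strand", "start",
                              "end", "mismatches", "three_prime_match",
                              "site_seq")
      else tibble(accession = character(0), primer = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  mismatches = integer(0), three_prime_match = logical(0),
                  site_seq = character(0)))()
}

#' Predict PCR products for a primer pair
#'
#' Enumerates every convergent forward/reverse site pairing within the length
#' cap — forward site on `+` with reverse site on `-` downstream, and the
#' mirror orientation — and reports each as one amplicon. No
#' "shortest-product" collapsing is done; downstream summaries deduplicate
#' per accession where needed. Under `require_three_prime` both sites must
#' have a compatible 3'-terminal base, the in-silico proxy for polymerase
#' extension being possible at all.
#'
#' @param pair A [primer_pair()].
#' @param refs Reference-set tibble.
#' @param policy A [match_policy()].
#' @return A tibble with one row per predicted product: `accession`,
#'   `species`, `group` (if present in `refs`), `orientation` (`+` if the
#'   forward primer binds the forward strand), forward/reverse site
#'   coordinates and diagnostics, primer-inclusive `length`, `product` and
#'   `insert` sequences (forward-primer orientation), `insert_length`, and
#'   insert `gc`.
#' @export
amplify <- function(pair, refs, policy = match_policy()) {
  stopifnot(inherits(pair, "primer_pair"), inherits(policy, "match_policy"))
  flen <- nchar(pair$forward$seq)
  rlen <- nchar(pair$reverse$seq)
  if (policy$max_amplicon_length <= flen + rlen) {
    stop("max_amplicon_length must exceed the summed primer lengths",
         call. = FALSE)
  }
  fsites <- find_binding_sites(pair$forward, refs, policy)
  rsites <- find_binding_sites(pair$reverse, refs, policy)
  empty <- tibble(accession = character(0), orientation = character(0),
                  fwd_start = integer(0), fwd_end = integer(0),
                  fwd_mm = integer(0), fwd_3p = logical(0),
                  rev_start = integer(0), rev_end = integer(0),
                  rev_mm = integer(0), rev_3p = logical(0),
                  length = integer(0), product = character(0),
                  insert = character(0), insert_length = integer(0),
                  gc = numeric(0))
  if (!nrow(fsites) || !nrow(rsites)) {
    return(.annotate_hits(empty, refs))
  }
  f <- fsites |>
    dplyr::rename(fwd_strand = "strand", fwd_start = "start",
                  fwd_end = "end", fwd_mm = "mismatches",
                  fwd_3p = "three_prime_match") |>
    select(-"primer", -"site_seq")
  r <- rsites |>
    dplyr::rename(rev_strand = "strand", rev_start = "start",
                  rev_end = "end", rev_mm = "mismatches",
                  rev_3p = "three_prime_match") |>
    select(-"primer", -"site_seq")
  pairs <- inner_join(f, r, by = "accession",
                      relationship = "many-to-many") |>
    filter(
      (.data$fwd_strand == "+" & .data$rev_strand == "-" &
         .data$rev_start >= .data$fwd_end &
         .data$rev_end - .data$fwd_start <= policy$max_amplicon_length) |
      (.data$fwd_strand == "-" & .data$rev_strand == "+" &
         .data$fwd_start >= .data$rev_end &
         .data$fwd_end - .data$rev_start <= policy$max_amplicon_length))
  if (policy$require_three_prime) {
    pairs <- filter(pairs, .data$fwd_3p, .data$rev_3p)
  }
  if (!nrow(pairs)) return(.annotate_hits(empty, refs))
  seq_of <- stats::setNames(refs$seq, refs$accession)
  pairs <- pairs |>
    mutate(orientation = ifelse(.data$fwd_strand == "+", "+", "-"),
           span_start = ifelse(.data$orientation == "+",
                               .data$fwd_start, .data$rev_start),
           span_end = ifelse(.data$orientation == "+",
                             .data$rev_end, .data$fwd_end),
           length = as.integer(.data$span_end - .data$span_start),
           product = substring(seq_of[.data$accession],
                               .data$span_start + 1L, .data$span_end),
           product = ifelse(.data$orientation == "-",
                            dna_revcomp(.data$product), .data$product),
           insert = substring(.data$product, flen + 1L,
                              .data$length - rlen),
           insert_length = as.integer(.data$length - flen - rlen),
           gc = gc_fraction(.data$insert)) |>
    select("accession", "orientation", "fwd_start", "fwd_end", "fwd_mm",
           "fwd_3p", "rev_start", "rev_end", "rev_mm", "rev_3p", "length",
           "product", "insert", "insert_length", "gc")
  .annotate_hits(pairs, refs)
}

.annotate_hits <- function(hits, refs) {
  ann <- refs |> select(any_of(c("accession", "species", "group")))
  out <- left_join(hits, ann, by = "accession")
  keep_front <- intersect(c("accession", "species", "group"), names(out))
  select(out, all_of(keep_front), dplyr::everything())
}
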