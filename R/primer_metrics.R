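# Coverage, logo and resolution summaries of in-silico PCR output.

# One site per accession: lowest mismatch count, then leftmost. Keeps
# multi-site entries from dominating logo and histogram counts.
.dedup_sites <- function(sites) {
  sites |>
    group_by(.data$accession) |>
    arrange(.data$mismatches, .data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
}

#' Position count matrices for binding-site logos
#'
#' Tallies the template base observed at each primer position (5'→3', primer
#' orientation) across entries, one matrix per group — the counts behind a
#' binding-site sequence logo. Each accession contributes exactly one site
#' (lowest mismatch count, ties broken leftmost). Degenerate template bases
#' are counted in an `other` row rather than split fractionally, so the
#' `A/C/G/T` rows stay integer and each position's total (including `other`)
#' equals the group's sequence count.
#'
#' @param primer The [primer()] the sites belong to.
#' @param sites Binding-site tibble from [find_binding_sites()].
#' @param group_of Named character vector mapping accession to group label,
#'   or `NULL` to pool everything under `"all"`.
#' @return A tibble in long form: `primer`, `group`, `position` (1-based,
#'   5'→3'), `base` (`A`, `C`, `G`, `T`, `other`), `count`, `n_sequences`.
#' @export
build_pcm <- function(primer, sites, group_of = NULL) {
  stopifnot(inherits(primer, "primer"))
  m <- nchar(primer$seq)
  if (!nrow(sites)) {
    return(tibble(primer = character(0), group = character(0),
                  position = integer(0), base = character(0),
                  count = integer(0), n_sequences = integer(0)))
  }
  if (any(nchar(sites$site_seq) != m)) {
    stop("site length differs from primer length (", m, ")", call. = FALSE)
  }
  sites <- .dedup_sites(sites)
  grp <- if (is.null(group_of)) rep("all", nrow(sites))
         else unname(group_of[sites$accession])
  if (anyNA(grp)) stop("accession(s) missing from group_of", call. = FALSE)
  chars <- matrix(unlist(strsplit(sites$site_seq, "", fixed = TRUE)),
                  nrow = nrow(sites), byrow = TRUE)
  long <- tibble(group = rep(grp, times = m),
                 position = rep(seq_len(m), each = nrow(sites)),
                 base = as.vector(chars))
  long |>
    mutate(base = ifelse(.data$base %in% c("A", "C", "G", "T"),
                         .data$base, "other")) |>
    count(.data$group, .data$position, .data$base, name = "count") |>
    tidyr::complete(group = unique(grp), position = seq_len(m),
                    base = c("A", "C", "G", "T", "other"),
                    fill = list(count = 0L)) |>
    group_by(.data$group) |>
    mutate(n_sequences = sum(.data$count) %/% m) |>
    ungroup() |>
    mutate(primer = primer$name) |>
    select("primer", "group", "position", "base", "count", "n_sequences") |>
    arrange(.data$group, .data$position, .data$base)
}

#' Per-group primer coverage table
#'
#' For each group: how many entries have a forward site, a reverse site,
#' both; how many have a forward site whose 3'-terminal base matches; and
#' how many amplify under the strict 3' criterion (at least one predicted
#' product with both 3' bases matching). Fractions are reported alongside
#' counts, `NA` for empty groups.
#'
#' @param refs Grouped reference-set tibble ([assign_groups()] already run).
#' @param sites Binding sites for *both* primers of `pair`, e.g.
#'   `bind_rows(find_binding_sites(pair$forward, ...),
#'   find_binding_sites(pair$reverse, ...))`.
#' @param hits Amplicon tibble from [amplify()] (any 3' policy; strictness is
#'   re-derived from the per-site flags).
#' @param pair The [primer_pair()] used.
#' @return One row per group: `group`, `n_total`, `n_fwd_site`, `n_rev_site`,
#'   `n_both_sites`, `n_forward_3p_match`, `n_strict_amplifiable`, and
#'   matching `frac_*` columns.
#' @export
coverage_table <- function(refs, sites, hits, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  if (anyNA(refs$group)) {
    stop("refs must be grouped first (assign_groups)", call. = FALSE)
  }
  acc_with <- function(x) unique(x$accession)
  fwd <- filter(sites, .data$primer == pair$forward$name)
  rev <- filter(sites, .data$primer == pair$reverse$name)
  strict <- filter(hits, .data$fwd_3p, .data$rev_3p)
  refs |>
    mutate(
      has_fwd = .data$accession %in% acc_with(fwd),
      has_rev = .data$accession %in% acc_with(rev),
      fwd_3p = .data$accession %in%
        acc_with(filter(fwd, .data$three_prime_match)),
      strict = .data$accession %in% acc_with(strict)) |>
    group_by(.data$group) |>
    summarise(
      n_total = n(),
      n_fwd_site = sum(.data$has_fwd),
      n_rev_site = sum(.data$has_rev),
      n_both_sites = sum(.data$has_fwd & .data$has_rev),
      n_forward_3p_match = sum(.data$fwd_3p),
      n_strict_amplifiable = sum(.data$strict),
      .groups = "drop") |>
    mutate(across(c("n_fwd_site", "n_rev_site", "n_both_sites",
                    "n_forward_3p_match", "n_strict_amplifiable"),
                  ~ ifelse(.data$n_total > 0, .x / .data$n_total, NA_real_),
                  .names = "frac_{sub('^n_', '', .col)}"))
}

#' Per-primer, per-group mismatch histograms
#'
#' Distribution of mismatch counts across entries (one best site per
#' accession, same deduplication as [build_pcm()]).
#'
#' @param refs Grouped reference-set tibble.
#' @param sites Binding-site tibble (may mix primers).
#' @return Tibble: `primer`, `group`, `mismatches`, `n`.
#' @export
mismatch_histogram <- function(refs, sites) {
  grp <- stats::setNames(refs$group, refs$accession)
  sites |>
    group_by(.data$primer) |>
    dplyr::group_modify(~ .dedup_sites(.x)) |>
    ungroup() |>
    mutate(group = unname(grp[.data$accession])) |>
    count(.data$primer, .data$group, .data$mismatches, name = "n")
}

#' Taxonomic resolution of predicted amplicons
#'
#' Quantifies how often amplicon sequence alone identifies a species.
#' Two conventions are provided, bracketing the plausible definitions:
#' * `species-unique` (default): a species is *resolved* iff none of its
#'   distinct insert sequences is also produced by another species; the score
#'   is resolved species / species with at least one amplicon. Chosen as the
#'   default because "species resolution" is naturally species-denominated.
#' * `amplicon-lca`: the score is distinct insert sequences produced by
#'   exactly one species / distinct insert sequences.
#'
#' @param hits Amplicon tibble from [amplify()].
#' @param species_of Named character vector accession→species, or `NULL` if
#'   `hits` already carries a `species` column.
#' @param mode `"species-unique"` or `"amplicon-lca"`.
#' @return One-row tibble: `rank`, `mode`, `value`, `n_resolved`,
#'   `n_species`, `n_amplicons`.
#' @export
resolution_score <- function(hits, species_of = NULL,
                             mode = c("species-unique", "amplicon-lca")) {
  mode <- match.arg(mode)
  if (!nrow(hits)) stop("no amplicon hits to score", call. = FALSE)
  if (!is.null(species_of)) {
    hits <- mutate(hits, species = unname(species_of[.data$accession]))
  }
  if (!"species" %in% names(hits) || anyNA(hits$species)) {
    stop("species unknown for some hits; supply species_of", call. = FALSE)
  }
  pairs <- distinct(hits, .data$species, .data$insert)
  per_insert <- pairs |> count(.data$insert, name = "n_species_with")
  if (mode == "species-unique") {
    shared <- per_insert |> filter(.data$n_species_with > 1L)
    unresolved <- pairs |>
      semi_join(shared, by = "insert") |>
      distinct(.data$species)
    n_species <- dplyr::n_distinct(pairs$species)
    n_res <- n_species - nrow(unresolved)
    value <- n_res / n_species
  } else {
    n_species <- dplyr::n_distinct(pairs$species)
    n_res <- sum(per_insert$n_species_with == 1L)
    value <- n_res / nrow(per_insert)
  }
  tibble(rank = "species", mode = mode, value = value,
         n_resolved = as.integer(n_res), n_species = n_species,
         n_amplicons = nrow(per_insert))
}

#' Restrict two hit sets to their shared species
#'
#' Comparing resolution between marker datasets is only fair on the species
#' both datasets contain; this trims each hit table to that intersection.
#'
#' @param hits_a,hits_b Amplicon tibbles with a `species` column.
#' @return A list with elements `a` and `b`, the restricted tibbles.
#' @export
shared_species_subset <- function(hits_a, hits_b) {
  shared <- intersect(unique(hits_a$species), unique(hits_b$species))
  list(a = filter(hits_a, .data$species %in% shared),
       b = filter(hits_b, .data$species %in% shared))
}

#' Per-group amplicon length and GC statistics
#'
#' Mean and sample standard deviation (n−1) of primer-inclusive length,
#' insert length, and insert GC fraction, per group.
#'
#' @param hits Amplicon tibble with a `group` column.
#' @return Tibble: `group`, `n`, `length_mean`, `length_sd`,
#'   `insert_length_mean`, `insert_length_sd`, `gc_mean`, `gc_sd`.
#' @export
amplicon_stats <- function(hits) {
  if (!nrow(hits)) stop("no amplicon hits", call. = FALSE)
  hits |>
    group_by(.data$group) |>
    summarise(n = n(),
              length_mean = mean(.data$length),
              length_sd = sd(.data$length),
              insert_length_mean = mean(.data$insert_length),
              insert_length_sd = sd(.data$insert_length),
              gc_mean = mean(.data$gc),
              gc_sd = sd(.data$gc),
              .groups = "drop")
}
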