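# Reference-set I/O: annotated sequences as a tibble, one row per entry.
# Columns: accession, species, <rank columns...>, group, seq. Iteration
# order is FASTA order and is preserved by every operation.

#' Read a taxonomically annotated reference set
#'
#' Loads reference sequences from FASTA and joins each record to its row in a
#' tab-separated taxonomy table. The FASTA id is the token before the first
#' whitespace; duplicate ids are an error. Sequences are uppercased and
#' validated against the IUPAC DNA alphabet (`U` and anything else rejected,
#' with the offending position reported).
#'
#' @param fasta_path Path to a FASTA file of reference sequences.
#' @param taxonomy_path Path to a TSV with header columns `accession` and
#'   `species`; any further columns are taken as taxonomic ranks (the shipped
#'   convention is `order`, `suborder`, `family`, but extra ranks are kept).
#' @return A tibble with one row per FASTA record, in file order: `accession`,
#'   `species`, rank columns, `group` (initially `NA`), `seq`.
#' @export
read_reference_set <- function(fasta_path, taxonomy_path) {
  # read as raw strings first so alphabet violations are reported with the
  # accession and offset, not a translation-table error
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("accession", "species") %in% names(tax))) {
    stop("taxonomy table must have 'accession' and 'species' columns",
         call. = FALSE)
  }
  missing <- setdiff(ids, tax$accession)
  if (length(missing)) {
    stop("no taxonomy row for accession(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seq_chr <- unname(as.character(seqs))
  seq_chr <- validate_dna(seq_chr, what = ids)
  out <- tibble(accession = ids) |>
    left_join(tax, by = "accession") |>
    mutate(group = NA_character_, seq = seq_chr)
  new_reference_set(out)
}

new_reference_set <- function(x) {
  stopifnot(all(c("accession", "species", "seq") %in% names(x)))
  if (anyDuplicated(x$accession)) {
    stop("accessions must be unique within a reference set", call. = FALSE)
  }
  as_tibble(x)
}

#' Write a reference set back to FASTA + taxonomy TSV
#'
#' Inverse of [read_reference_set()]: round-tripping preserves accessions,
#' sequences and lineages exactly.
#'
#' @param refs Reference-set tibble.
#' @param fasta_path,taxonomy_path Output paths.
#' @return `refs`, invisibly.
#' @export
write_reference_set <- function(refs, fasta_path, taxonomy_path) {
  seqs <- Biostrings::DNAStringSet(refs$seq)
  names(seqs) <- refs$accession
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  tax <- refs |> select(-"seq", -"group")
  readr::write_tsv(tax, taxonomy_path, progress = FALSE)
  invisible(refs)
}

#' Define one bin of a grouping scheme
#'
#' A bin is a label plus a rank-equality predicate; a bin with no `rank`
#' matches everything (catch-all). Bins are tested in order and the first
#' match wins, so e.g. `Culicidae` can be peeled off before a broader
#' `Nematocera` bin.
#'
#' @param label Group label assigned to matching entries.
#' @param rank Name of the taxonomy column tested, or `NULL` for a catch-all.
#' @param value Value the rank must equal.
#' @return A `group_bin` object.
#' @export
group_bin <- function(label, rank = NULL, value = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (xor(is.null(rank), is.null(value))) {
    stop("give both 'rank' and 'value', or neither (catch-all)",
         call. = FALSE)
  }
  structure(list(label = label, rank = rank, value = value),
            class = "group_bin")
}

#' Assemble an ordered grouping scheme
#'
#' @param ... `group_bin` objects, most specific first. The last bin must be
#'   a catch-all so that every entry receives exactly one label.
#' @return A `grouping_scheme` object (list of bins).
#' @export
grouping_scheme <- function(...) {
  bins <- list(...)
  if (!length(bins) || !all(vapply(bins, inherits, logical(1), "group_bin"))) {
    stop("supply one or more group_bin() objects", call. = FALSE)
  }
  last <- bins[[length(bins)]]
  if (!is.null(last$rank)) {
    stop("the final bin must be a catch-all (no rank predicate)",
         call. = FALSE)
  }
  structure(bins, class = "grouping_scheme")
}

#' The default mosquito-surveillance grouping
#'
#' Splits arthropod references into the bins conventionally compared when
#' evaluating Culicidae-restricted primers: Culicidae; all other Nematocera;
#' the bycatch-prone orders Hymenoptera, Lepidoptera and Coleoptera; and a
#' catch-all for every remaining arthropod.
#'
#' @return A `grouping_scheme`.
#' @export
culicid_grouping <- function() {
  grouping_scheme(
    group_bin("Culicidae", "family", "Culicidae"),
    group_bin("non-culicid Nematocera", "suborder", "Nematocera"),
    group_bin("Hymenoptera", "order", "Hymenoptera"),
    group_bin("Lepidoptera", "order", "Lepidoptera"),
    group_bin("Coleoptera", "order", "Coleoptera"),
    group_bin("all other arthropods")
  )
}

#' Assign every reference entry to a group
#'
#' Applies the scheme's bins in order; the first matching bin labels the
#' entry, so the labels partition the set. Per-label counts are reported via
#' `message()`.
#'
#' @param refs Reference-set tibble.
#' @param scheme A [grouping_scheme()]; defaults to [culicid_grouping()].
#' @param quiet Suppress the per-label count message.
#' @return `refs` with the `group` column filled.
#' @export
assign_groups <- function(refs, scheme = culicid_grouping(), quiet = FALSE) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  lab <- rep(NA_character_, nrow(refs))
  for (bin in scheme) {
    if (is.null(bin$rank)) {
      hit <- rep(TRUE, nrow(refs))
    } else if (bin$rank %in% names(refs)) {
      hit <- !is.na(refs[[bin$rank]]) & refs[[bin$rank]] == bin$value
    } else {
      hit <- rep(FALSE, nrow(refs))
    }
    lab[is.na(lab) & hit] <- bin$label
  }
  refs$group <- lab
  if (!quiet) {
    tab <- table(factor(lab, levels = unique(vapply(scheme, `[[`, "", "label"))))
    message("group counts: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  refs
}

#' Keep entries with enough flanking sequence around a binding site
#'
#' Retains entries having at least one located binding site with `min_flank`
#' or more residues both upstream and downstream of the site — the guard
#' against database submissions whose termini are untrimmed amplification
#' primers. Coordinates are 0-based half-open on the forward strand, so the
#' upstream flank is `start` and the downstream flank is `nchar(seq) - end`.
#'
#' @param refs Reference-set tibble.
#' @param sites Binding-site tibble from [find_binding_sites()] for these
#'   entries.
#' @param min_flank Minimum flank length in residues (default 30).
#' @return The filtered reference set (possibly empty), original order.
#' @export
filter_by_flank <- function(refs, sites, min_flank = 30L) {
  stopifnot(min_flank >= 0L)
  if (!nrow(sites)) return(refs[0, , drop = FALSE])
  lens <- tibble(accession = refs$accession, .len = nchar(refs$seq))
  keep <- sites |>
    inner_join(lens, by = "accession") |>
    filter(.data$start >= min_flank, .data$.len - .data$end >= min_flank) |>
    distinct(.data$accession)
  refs |> semi_join(keep, by = "accession")
}
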