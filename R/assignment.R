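# Per-specimen variant libraries and exact-identity read assignment.

#' Remove minor variants from one specimen's counts
#'
#' Within a single specimen's denoised variant counts, drops variants
#' representing *fewer than* `threshold` of the total — the guard against
#' trace cross-contamination between specimens processed together (e.g.
#' collected in the same trap). A variant at exactly the threshold is kept.
#'
#' @param variant_counts Tibble with columns `seq` and `count`, or a named
#'   numeric vector (names = sequences).
#' @param threshold Minimum retained fraction of the specimen total
#'   (default 0.01).
#' @return Same shape as the input, minor variants removed.
#' @export
filter_minor_variants <- function(variant_counts, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1)
  vec_in <- !is.data.frame(variant_counts)
  tbl <- if (vec_in) {
    tibble(seq = names(variant_counts), count = as.numeric(variant_counts))
  } else {
    as_tibble(variant_counts)
  }
  stopifnot(all(c("seq", "count") %in% names(tbl)), all(tbl$count >= 0))
  total <- sum(tbl$count)
  if (total == 0) stop("all variant counts are zero", call. = FALSE)
  keep <- tbl$count / total >= threshold
  out <- tbl[keep, , drop = FALSE]
  if (vec_in) stats::setNames(out$count, out$seq) else out
}

#' Build an exact-match reference library from per-specimen variants
#'
#' Collates pre-filtered variants into a species→variant library with
#' per-variant provenance (specimen, within-individual frequency). The
#' defining invariant — no variant sequence shared between species — is
#' enforced; a violation signals contamination or a defective mock dataset
#' and is a hard error naming both species.
#'
#' @param per_specimen_variants Tibble with columns `species`, `specimen`,
#'   `seq`, and either `freq` (within-specimen frequencies) or `count`
#'   (converted to frequencies per specimen).
#' @return Tibble: `species`, `specimen`, `variant_id`, `seq`, `freq`.
#' @export
build_library <- function(per_specimen_variants) {
  tbl <- as_tibble(per_specimen_variants)
  stopifnot(all(c("species", "specimen", "seq") %in% names(tbl)))
  if (!"freq" %in% names(tbl)) {
    if (!"count" %in% names(tbl)) {
      stop("supply a 'freq' or 'count' column", call. = FALSE)
    }
    tbl <- tbl |>
      group_by(.data$specimen) |>
      mutate(freq = .data$count / sum(.data$count)) |>
      ungroup()
  }
  tbl <- mutate(tbl, seq = validate_dna(.data$seq))
  clash <- tbl |>
    distinct(.data$species, .data$seq) |>
    count(.data$seq, name = "n_species") |>
    filter(.data$n_species > 1L)
  if (nrow(clash)) {
    offenders <- tbl |>
      semi_join(clash, by = "seq") |>
      arrange(.data$seq) |>
      group_by(.data$seq) |>
      summarise(who = paste(sort(unique(.data$species)), collapse = " / "),
                .groups = "drop")
    stop("variant sequence shared between species: ",
         paste(offenders$who, collapse = "; "), call. = FALSE)
  }
  tbl |>
    group_by(.data$species) |>
    mutate(variant_id = sprintf("%s.v%02d", .data$species, row_number())) |>
    ungroup() |>
    select("species", "specimen", "variant_id", "seq", "freq")
}

#' Assign reads to species by exact identity
#'
#' A read is assigned iff it is character-identical (after uppercasing, full
#' length) to a library variant; anything else — bycatch, chimeras, reads
#' with errors — is `"unassigned"`. Assignment is order-independent and
#' idempotent.
#'
#' @param reads Character vector of read sequences, or a tibble with a `seq`
#'   column (other columns, e.g. `read_id` or `pool`, pass through).
#' @param lib Library tibble from [build_library()].
#' @return The reads tibble with a `species` column added (`"unassigned"`
#'   where no variant matches).
#' @export
assign_reads <- function(reads, lib) {
  tbl <- if (is.data.frame(reads)) as_tibble(reads)
         else tibble(seq = as.character(reads))
  stopifnot("seq" %in% names(tbl))
  lookup <- stats::setNames(lib$species, lib$seq)
  tbl |>
    mutate(species = unname(lookup[toupper(.data$seq)]),
           species = ifelse(is.na(.data$species), "unassigned",
                            .data$species))
}

#' Tally an assignment into per-species read counts
#'
#' @param assigned Output of [assign_reads()].
#' @param by Extra grouping columns (e.g. `"pool"`) present in `assigned`.
#' @return Tibble of read counts per species (and `by` groups), including an
#'   `"unassigned"` row when applicable; counts sum to the number of reads.
#' @export
tally_assignments <- function(assigned, by = character(0)) {
  assigned |>
    count(across(all_of(c(by, "species"))), name = "reads") |>
    arrange(across(all_of(c(by, "species"))))
}

#' Write / read a variant library as FASTA
#'
#' Headers encode provenance as `species|specimen|freq`.
#'
#' @param lib Library tibble.
#' @param path FASTA path.
#' @return `lib` invisibly (write) or the parsed library tibble (read).
#' @export
write_library <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(lib$seq)
  names(seqs) <- sprintf("%s|%s|%.6f", lib$species, lib$specimen, lib$freq)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(lib)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3L)
  build_library(tibble(species = parts[, 1], specimen = parts[, 2],
                       seq = unname(as.character(seqs)),
                       freq = as.numeric(parts[, 3])))
}
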