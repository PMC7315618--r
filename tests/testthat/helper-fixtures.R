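# Small in-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a FASTA + taxonomy TSV pair into tempdir and return the two paths.
write_ref_fixture <- function(seqs, species = NULL, order = NULL,
                              suborder = NULL, family = NULL,
                              ids = names(seqs)) {
  n <- length(seqs)
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", unname(seqs)), fa)
  tax <- tempfile(fileext = ".tsv")
  tbl <- data.frame(
    accession = ids,
    species = species %||% paste0("Species_", seq_len(n)),
    order = order %||% rep("Diptera", n),
    suborder = suborder %||% rep("Nematocera", n),
    family = family %||% rep("Culicidae", n))
  write.table(tbl, tax, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, taxonomy = tax)
}

# Reference-set tibble built directly (skipping file I/O).
make_refs <- function(seqs, species = NULL, group = NA_character_, ...) {
  n <- length(seqs)
  tibble::tibble(
    accession = names(seqs) %||% sprintf("ACC%03d", seq_len(n)),
    species = species %||% paste0("Species_", seq_len(n)),
    ...,
    group = rep_len(group, n),
    seq = unname(seqs))
}

# Random DNA with a given fraction of degenerate IUPAC codes.
random_seq <- function(n, degenerate_frac = 0) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (degenerate_frac > 0) {
    k <- rbinom(1, n, degenerate_frac)
    if (k > 0) {
      pos <- sample(n, k)
      base[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), k,
                          replace = TRUE)
    }
  }
  paste(base, collapse = "")
}

# Mutate `k` random positions of a sequence (substitutions to a different
# plain base).
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (k > 0) {
    for (pos in sample(length(ch), min(k, length(ch)))) {
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    }
  }
  paste(ch, collapse = "")
}

d2_pair <- ampliscope::mozzie_d2_primers()
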