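# Independent brute-force in-silico PCR oracle. Deliberately written on a
# different route from the package engine: the minus strand is handled by
# reverse-complementing each *window* (not the primer), mismatches are
# counted in an explicit double loop, and the IUPAC table is spelled out
# locally.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_compat <- function(a, b) {
  length(intersect(oracle_iupac[[a]], oracle_iupac[[b]])) > 0
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
}

# All sites of one primer on both strands of one template; 0-based half-open
# forward-strand coordinates.
oracle_scan <- function(primer_seq, template, max_mm) {
  p <- strsplit(primer_seq, "", fixed = TRUE)[[1]]
  m <- length(p)
  n <- nchar(template)
  out <- list()
  if (n < m) return(out)
  for (i in seq_len(n - m + 1)) {
    win <- substr(template, i, i + m - 1)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else oracle_revcomp(win)
      wch <- strsplit(w, "", fixed = TRUE)[[1]]
      mm <- 0L
      for (j in seq_len(m)) {
        if (!oracle_compat(p[j], wch[j])) mm <- mm + 1L
      }
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- list(
          strand = strand, start = i - 1L, end = i - 1L + m, mm = mm,
          tp = oracle_compat(p[m], wch[m]))
      }
    }
  }
  out
}

# All products of a primer pair on one template, as a data.frame of
# (orientation, span start/end, product sequence).
oracle_amplify <- function(fwd_seq, rev_seq, template, max_mm, require_3p,
                           max_len) {
  fs <- oracle_scan(fwd_seq, template, max_mm)
  rs <- oracle_scan(rev_seq, template, max_mm)
  rows <- list()
  for (f in fs) {
    for (r in rs) {
      if (require_3p && !(f$tp && r$tp)) next
      if (f$strand == "+" && r$strand == "-" &&
          r$start >= f$end && r$end - f$start <= max_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          orientation = "+", start = f$start, end = r$end,
          product = substr(template, f$start + 1, r$end))
      } else if (f$strand == "-" && r$strand == "+" &&
                 f$start >= r$end && f$end - r$start <= max_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          orientation = "-", start = r$start, end = f$end,
          product = oracle_revcomp(substr(template, r$start + 1, f$end)))
      }
    }
  }
  if (!length(rows)) {
    data.frame(orientation = character(0), start = integer(0),
               end = integer(0), product = character(0))
  } else {
    do.call(rbind, rows)
  }
}

# Canonical signature of a hit set for set comparison.
hit_signature <- function(acc, orientation, start, end, product) {
  sort(paste(acc, orientation, start, end, product, sep = ":"))
}

# Sequences that actually exercise the engine: random background with a
# planted, mutated forward site + insert + reverse site, sometimes flipped
# to the other strand, sometimes with a second forward site, plus a fraction
# of degenerate bases in the background.
make_oracle_case <- function(pair, degenerate_frac = 0.1) {
  fwd <- pair$forward$seq
  rev <- pair$reverse$seq
  f_site <- mutate_seq(fwd, sample(0:7, 1))
  r_site <- mutate_seq(rev, sample(0:7, 1))
  insert <- random_seq(sample(40:220, 1), degenerate_frac)
  core <- paste0(f_site, insert, oracle_revcomp(r_site))
  if (runif(1) < 0.25) {
    core <- paste0(mutate_seq(fwd, sample(0:5, 1)),
                   random_seq(sample(20:60, 1), degenerate_frac), core)
  }
  s <- paste0(random_seq(sample(5:40, 1), degenerate_frac), core,
              random_seq(sample(5:40, 1), degenerate_frac))
  if (runif(1) < 0.5) s <- oracle_revcomp(s)
  substr(s, 1, 400)
}
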