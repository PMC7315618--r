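# Generative models: D2-like reference sets with planted clade-diagnostic
# priming sites, and multinomial pooled-read simulation with amplifiability
# heterogeneity, degradation, bycatch saturation and carryover contamination.

.random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# 1-3 SNPs, optionally one short tandem duplication/deletion (the
# microsatellite-style indels seen among within-individual rDNA variants).
.mutate_insert <- function(seq, indel_prob) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (pos in sample(length(ch), sample(1:3, 1))) {
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
  }
  if (runif(1) < indel_prob && length(ch) > 20L) {
    w <- sample(2:6, 1)
    at <- sample(length(ch) - w, 1)
    if (runif(1) < 0.5) {
      ch <- append(ch, ch[at:(at + w - 1L)], after = at + w - 1L)
    } else {
      ch <- ch[-(at:(at + w - 1L))]
    }
  }
  paste(ch, collapse = "")
}

#' Configuration for the synthetic reference generator
#'
#' Defaults emulate the D2 marker system: two target clades with insert
#' lengths 383 (SD 9) and 432 (SD 24) nt at GC 0.60, a conserved reverse
#' priming site shared by everything, and a forward site whose 3'-terminal
#' base alone separates target from non-target clades. Each target species is
#' one specimen carrying 1–6 intragenomic variants.
#'
#' @param n_target_species Number of target (Culicidae-like) species.
#' @param clade_b_species How many of those belong to the longer-insert
#'   clade (anopheline-like); the remainder use `insert_len_a`.
#' @param offtarget_sizes Named integer vector: species per off-target group.
#'   Names feed the taxonomy so [culicid_grouping()] reproduces them.
#' @param insert_len_a,insert_len_b `c(mean, sd)` of insert length per target
#'   clade.
#' @param insert_gc Target insert GC fraction.
#' @param variants_range `c(min, max)` intragenomic variants per specimen.
#' @param indel_prob Probability a non-dominant variant carries a
#'   microsatellite-style indel in addition to SNPs.
#' @param flank Plain-sequence padding either side of the priming sites (nt).
#' @param pair The [primer_pair()] whose sites are planted.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `synth_ref_config` list.
#' @export
synth_ref_config <- function(n_target_species = 17L, clade_b_species = 3L,
                             offtarget_sizes = c("non-culicid Nematocera" = 6L,
                                                 "Hymenoptera" = 4L,
                                                 "Lepidoptera" = 4L,
                                                 "Coleoptera" = 4L,
                                                 "all other arthropods" = 6L),
                             insert_len_a = c(mean = 383, sd = 9),
                             insert_len_b = c(mean = 432, sd = 24),
                             insert_gc = 0.60,
                             variants_range = c(1L, 6L),
                             indel_prob = 0.3,
                             flank = 30L,
                             pair = mozzie_d2_primers(),
                             seed = 1L) {
  offtarget_sizes <- unlist(offtarget_sizes)
  stopifnot(n_target_species >= 1L,
            clade_b_species >= 0L, clade_b_species <= n_target_species,
            all(offtarget_sizes >= 0L),
            insert_len_a[1] > 0, insert_len_b[1] > 0,
            insert_gc > 0, insert_gc < 1,
            length(variants_range) == 2L,
            variants_range[1] >= 1L,
            variants_range[2] >= variants_range[1],
            indel_prob >= 0, indel_prob <= 1, flank >= 0L,
            inherits(pair, "primer_pair"))
  structure(list(n_target_species = as.integer(n_target_species),
                 clade_b_species = as.integer(clade_b_species),
                 offtarget_sizes = offtarget_sizes,
                 insert_len_a = insert_len_a, insert_len_b = insert_len_b,
                 insert_gc = insert_gc,
                 variants_range = as.integer(variants_range),
                 indel_prob = indel_prob, flank = as.integer(flank),
                 pair = pair, seed = as.integer(seed)),
            class = "synth_ref_config")
}

# Taxonomy templates for the off-target groups (rank-equality predicates
# that culicid_grouping() recognises).
.offtarget_taxa <- list(
  "non-culicid Nematocera" = list(order = "Diptera", suborder = "Nematocera",
                                  family = "Chaoboridae"),
  "Hymenoptera" = list(order = "Hymenoptera", suborder = "Apocrita",
                       family = "Formicidae"),
  "Lepidoptera" = list(order = "Lepidoptera", suborder = "Glossata",
                       family = "Noctuidae"),
  "Coleoptera" = list(order = "Coleoptera", suborder = "Polyphaga",
                      family = "Carabidae"),
  "all other arthropods" = list(order = "Araneae", suborder = NA_character_,
                                family = "Salticidae"))

#' Generate a synthetic reference set with planted primer sites
#'
#' Target entries carry both priming sites exactly; off-target entries carry
#' the conserved reverse site plus a forward site whose 3'-terminal base is
#' incompatible with the forward primer's 3' base (and up to two further
#' internal substitutions) — so under a strict 3' policy exactly the target
#' clade amplifies, while relaxing the criterion admits the off-targets.
#' Inserts are unique per species; each target specimen additionally gets
#' 1–6 intragenomic variants (SNPs, occasional microsatellite indels) with
#' within-individual frequencies, forming the assignment library.
#' Deterministic under `cfg$seed`.
#'
#' @param cfg A [synth_ref_config()].
#' @return A list: `refs` (grouped reference-set tibble), `library`
#'   (tibble from [build_library()], insert sequences), `pair`, `config`.
#' @export
synth_reference_set <- function(cfg = synth_ref_config()) {
  stopifnot(inherits(cfg, "synth_ref_config"))
  fwd <- cfg$pair$forward$seq
  rev <- cfg$pair$reverse$seq
  fwd_ch <- strsplit(fwd, "", fixed = TRUE)[[1]]
  m <- length(fwd_ch)
  # an off-target 3' base: incompatible with the primer's 3' base
  three_p <- fwd_ch[m]
  off_base <- setdiff(c("A", "C", "G", "T"),
                      .iupac_sets[[three_p]])[1]
  withr::with_seed(cfg$seed, {
    seen <- character(0)
    draw_insert <- function(len_mean, len_sd) {
      repeat {
        len <- max(50L, round(rnorm(1, len_mean, len_sd)))
        s <- .random_dna(len, cfg$insert_gc)
        if (!s %in% seen) {
          seen <<- c(seen, s)
          return(s)
        }
      }
    }
    n_b <- cfg$clade_b_species
    n_a <- cfg$n_target_species - n_b
    targets <- tibble(
      species = c(sprintf("Culicine_sp_%02d", seq_len(n_a)),
                  if (n_b > 0) sprintf("Anopheline_sp_%02d", seq_len(n_b))),
      clade = c(rep("A", n_a), rep("B", n_b)))
    targets$insert <- purrr::map_chr(targets$clade, function(cl) {
      if (cl == "A") draw_insert(cfg$insert_len_a[1], cfg$insert_len_a[2])
      else draw_insert(cfg$insert_len_b[1], cfg$insert_len_b[2])
    })
    offtargets <- purrr::imap(cfg$offtarget_sizes, function(n_sp, grp) {
      if (n_sp == 0L) return(NULL)
      tax <- .offtarget_taxa[[grp]] %||%
        list(order = grp, suborder = NA_character_, family = grp)
      tibble(species = sprintf("%s_sp_%02d", gsub("[^A-Za-z]+", "_", grp),
                               seq_len(n_sp)),
             group_hint = grp, order = tax$order, suborder = tax$suborder,
             family = tax$family)
    }) |> purrr::compact() |> bind_rows()
    if (nrow(offtargets)) {
      offtargets$insert <- purrr::map_chr(seq_len(nrow(offtargets)),
        function(i) draw_insert(420, 60))
      # forward site: diagnostic 3' base plus 0-2 internal substitutions
      offtargets$fwd_site <- purrr::map_chr(seq_len(nrow(offtargets)),
        function(i) {
          ch <- fwd_ch
          ch[m] <- off_base
          k <- sample(0:2, 1)
          if (k > 0) {
            for (pos in sample(m - 1L, k)) {
              ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
            }
          }
          paste(ch, collapse = "")
        })
    }
    mk_entry <- function(fwd_site, insert) {
      paste0(.random_dna(cfg$flank, 0.5), fwd_site, insert,
             dna_revcomp(rev), .random_dna(cfg$flank, 0.5))
    }
    target_refs <- targets |>
      mutate(order = "Diptera", suborder = "Nematocera",
             family = "Culicidae",
             seq = purrr::map_chr(.data$insert, ~ mk_entry(fwd, .x)))
    off_refs <- if (nrow(offtargets)) {
      offtargets |>
        mutate(seq = purrr::map2_chr(.data$fwd_site, .data$insert, mk_entry))
    } else NULL
    refs <- bind_rows(
      select(target_refs, "species", "order", "suborder", "family", "seq"),
      if (!is.null(off_refs)) {
        select(off_refs, "species", "order", "suborder", "family", "seq")
      }) |>
      mutate(accession = sprintf("SYN%04d", row_number()), .before = 1)
    refs <- new_reference_set(refs) |>
      assign_groups(culicid_grouping(), quiet = TRUE)
    # intragenomic variant library for the target specimens
    lib <- purrr::pmap(targets, function(species, clade, insert) {
      n_var <- sample(seq(cfg$variants_range[1], cfg$variants_range[2]), 1)
      vars <- insert
      while (length(vars) < n_var) {
        v <- .mutate_insert(insert, cfg$indel_prob)
        if (!v %in% seen) {
          seen <<- c(seen, v)
          vars <- c(vars, v)
        }
      }
      w <- c(1, if (n_var > 1) runif(n_var - 1, 0.05, 0.6))
      tibble(species = species, specimen = species, seq = vars,
             freq = w / sum(w))
    }) |> bind_rows() |> build_library()
    list(refs = refs, library = lib, pair = cfg$pair, config = cfg)
  })
}

#' Specimen amplifiability/degradation models
#'
#' @param species Character vector of species.
#' @param amplifiability Amplifiable-template units per µL of stock (> 0);
#'   recycled.
#' @param degradation Multiplicative retention of amplifiable template in
#'   `(0, 1]` (1 = fresh stock); recycled.
#' @return Tibble `species`, `amplifiability`, `degradation`.
#' @export
specimen_models <- function(species, amplifiability = 1, degradation = 1) {
  stopifnot(all(amplifiability > 0), all(degradation > 0),
            all(degradation <= 1))
  tibble(species = species,
         amplifiability = rep_len(amplifiability, length(species)),
         degradation = rep_len(degradation, length(species)))
}

#' Mock pool designs with volumes spanning two orders of magnitude
#'
#' Builds `n_pools` designs over the same species, per-specimen volumes drawn
#' log-uniformly in `vol_range` (default 0.5–40 µL, the conventional span for
#' mock assemblages whose members range over two orders of magnitude).
#'
#' @param species Character vector of pool members.
#' @param n_pools Number of replicate pools (labelled `Pool_A`, `Pool_B`, ...).
#' @param vol_range `c(min, max)` volume in µL.
#' @param seed Integer seed.
#' @return Tibble `pool`, `species`, `volume_ul`.
#' @export
fresh_pool_design <- function(species, n_pools = 4L, vol_range = c(0.5, 40),
                              seed = 1L) {
  stopifnot(n_pools >= 1L, vol_range[1] > 0, vol_range[2] >= vol_range[1])
  withr::with_seed(seed, {
    purrr::map(seq_len(n_pools), function(i) {
      tibble(pool = paste0("Pool_", LETTERS[i]), species = species,
             volume_ul = round(exp(runif(length(species),
                                         log(vol_range[1]),
                                         log(vol_range[2]))), 2))
    }) |> bind_rows()
  })
}

#' Configuration for pooled-read simulation
#'
#' @param design Pool design tibble (`pool`, `species`, `volume_ul`).
#' @param specimens [specimen_models()] tibble; default: every design species
#'   at amplifiability 1, degradation 1.
#' @param depth Target post-quality-filter read depth per pool.
#' @param bycatch_dna_ratio Volumes of bycatch DNA mixed per volume of target
#'   pool (0 = pure pool; 1 and 10 are the conventional mix designs).
#' @param carryover_fraction Fraction of the bycatch's amplifiable template
#'   that is actually target-species carryover (loose scales, antennae and
#'   other tissue fragments surviving bycatch cleanup).
#' @param bycatch_families Named weights for the amplifying bycatch
#'   categories (default dominated by Chaoboridae, the family closest to
#'   Culicidae).
#' @param bycatch_unit_mass Amplifiable template mass of one volume unit of
#'   bycatch DNA; default = the pool's total target amplifiable mass, so
#'   `bycatch_dna_ratio` directly sets the amplifiable bycatch:target odds.
#' @param contaminant_species Species receiving the carryover mass (split
#'   equally); default: the design's first species.
#' @param quality_loss Fraction of raw sequencing output discarded by quality
#'   filtering (default 0.20).
#' @param seed Integer seed; per-pool streams are derived from it.
#' @return A `pool_sim_config` list.
#' @export
pool_sim_config <- function(design, specimens = NULL, depth = 17000L,
                            bycatch_dna_ratio = 0,
                            carryover_fraction = 0,
                            bycatch_families = c(Chaoboridae = 0.70,
                                                 Chironomidae = 0.15,
                                                 Simuliidae = 0.10,
                                                 Ceratopogonidae = 0.05),
                            bycatch_unit_mass = NULL,
                            contaminant_species = NULL,
                            quality_loss = 0.20, seed = 1L) {
  design <- as_tibble(design)
  stopifnot(all(c("pool", "species", "volume_ul") %in% names(design)),
            all(design$volume_ul > 0), depth >= 1L,
            bycatch_dna_ratio >= 0,
            carryover_fraction >= 0, carryover_fraction <= 1,
            quality_loss >= 0, quality_loss < 1,
            all(bycatch_families >= 0))
  if (is.null(specimens)) specimens <- specimen_models(unique(design$species))
  missing <- setdiff(design$species, specimens$species)
  if (length(missing)) {
    stop("no specimen model for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(design = design, specimens = as_tibble(specimens),
                 depth = as.integer(depth),
                 bycatch_dna_ratio = bycatch_dna_ratio,
                 carryover_fraction = carryover_fraction,
                 bycatch_families = bycatch_families / sum(bycatch_families),
                 bycatch_unit_mass = bycatch_unit_mass,
                 contaminant_species = contaminant_species,
                 quality_loss = quality_loss, seed = as.integer(seed)),
            class = "pool_sim_config")
}

#' True read-generating proportions of a simulated pool
#'
#' Target species mass is `volume x amplifiability x degradation`. With
#' bycatch mixed at ratio `r`, a further `r` units of bycatch mass join the
#' pool, of which `carryover_fraction` is reassigned to the contaminant
#' target species and the remainder is spread over the bycatch families by
#' their weights. Proportions are the normalized masses.
#'
#' @param config A [pool_sim_config()].
#' @return Tibble `pool`, `species`, `provenance`
#'   (`target`/`bycatch`/`contaminant`), `prop`; proportions sum to 1 within
#'   each pool.
#' @export
true_proportions <- function(config) {
  stopifnot(inherits(config, "pool_sim_config"))
  purrr::map(unique(config$design$pool), function(p) {
    d <- filter(config$design, .data$pool == p) |>
      left_join(config$specimens, by = "species")
    mass <- d$volume_ul * d$amplifiability * d$degradation
    total_t <- sum(mass)
    if (total_t <= 0) stop("pool ", p, " has zero amplifiable mass",
                           call. = FALSE)
    rows <- tibble(pool = p, species = d$species, provenance = "target",
                   mass = mass)
    r <- config$bycatch_dna_ratio
    if (r > 0) {
      bmass <- r * (config$bycatch_unit_mass %||% total_t)
      carry <- bmass * config$carryover_fraction
      if (carry > 0) {
        contam <- config$contaminant_species %||% d$species[1]
        rows <- bind_rows(rows,
          tibble(pool = p, species = contam, provenance = "contaminant",
                 mass = carry / length(contam)))
      }
      fam <- config$bycatch_families
      rows <- bind_rows(rows,
        tibble(pool = p, species = names(fam), provenance = "bycatch",
               mass = bmass * (1 - config$carryover_fraction) * unname(fam)))
    }
    mutate(rows, prop = .data$mass / sum(.data$mass)) |>
      select("pool", "species", "provenance", "prop")
  }) |> bind_rows()
}

#' Simulate pooled amplicon read counts
#'
#' For each pool: draw a raw depth `N' = round(depth / (1 - quality_loss))`,
#' discard reads binomially at `quality_loss` (emulating quality filtering),
#' then allocate the surviving reads multinomially across the pool's
#' generating categories from [true_proportions()]. Deterministic given the
#' config seed (pool `i` uses stream `seed + i`).
#'
#' @param config A [pool_sim_config()].
#' @return A `simulated_run` list: `reads` (tibble `pool`, `species`,
#'   `reads`, summed over provenance), `provenance` (per-category counts),
#'   `truth` (the generating proportions), `depth` (raw/discarded/realized
#'   per pool), `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "pool_sim_config"))
  truth <- true_proportions(config)
  pools <- unique(config$design$pool)
  prov <- purrr::imap(pools, function(p, i) {
    tp <- filter(truth, .data$pool == p)
    withr::with_seed(config$seed + i, {
      raw <- round(config$depth / (1 - config$quality_loss))
      discarded <- rbinom(1, raw, config$quality_loss)
      realized <- raw - discarded
      counts <- as.vector(rmultinom(1, realized, tp$prop))
    })
    list(counts = mutate(tp, reads = counts) |> select(-"prop"),
         depth = tibble(pool = p, raw_depth = raw, discarded = discarded,
                        realized_depth = realized))
  })
  provenance <- bind_rows(purrr::map(prov, "counts"))
  reads <- provenance |>
    group_by(.data$pool, .data$species) |>
    summarise(reads = sum(.data$reads), .groups = "drop")
  structure(list(reads = reads, provenance = provenance, truth = truth,
                 depth = bind_rows(purrr::map(prov, "depth")),
                 config = config),
            class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf(
    "<simulated_run> %d pool(s), target depth %d (quality loss %.0f%%), seed %d\n",
    dplyr::n_distinct(x$reads$pool), x$config$depth,
    100 * x$config$quality_loss, x$config$seed))
  print(x$depth)
  invisible(x)
}

#' Expand simulated counts into read sequences
#'
#' Turns a [simulate_reads()] run into per-read sequences for exact-identity
#' assignment: reads of target or contaminant provenance are distributed over
#' that species' library variants multinomially by within-individual
#' frequency; bycatch reads take the family's sequence from
#' `bycatch_variants` (or a deterministic random surrogate absent from any
#' library, if not supplied). No sequencing error is applied.
#'
#' @param run A `simulated_run`.
#' @param lib Library tibble from [build_library()].
#' @param bycatch_variants Optional tibble `species`, `seq` for the bycatch
#'   categories.
#' @param seed Integer seed for the variant allocation.
#' @return Tibble `pool`, `read_id`, `seq`, `true_species`, `provenance`.
#' @export
expand_read_sequences <- function(run, lib, bycatch_variants = NULL,
                                  seed = 1L) {
  stopifnot(inherits(run, "simulated_run"))
  withr::with_seed(seed, {
    out <- purrr::pmap(run$provenance,
      function(pool, species, provenance, reads) {
        if (reads == 0L) return(NULL)
        if (provenance %in% c("target", "contaminant")) {
          v <- filter(lib, .data$species == !!species)
          if (!nrow(v)) stop("species '", species, "' missing from library",
                             call. = FALSE)
          alloc <- as.vector(rmultinom(1, reads, v$freq))
          tibble(pool = pool, seq = rep(v$seq, alloc),
                 true_species = species, provenance = provenance)
        } else {
          s <- if (!is.null(bycatch_variants) &&
                   species %in% bycatch_variants$species) {
            bycatch_variants$seq[match(species, bycatch_variants$species)]
          } else {
            .random_dna(400, 0.5)
          }
          tibble(pool = pool, seq = rep(s, reads),
                 true_species = species, provenance = provenance)
        }
      }) |> purrr::compact() |> bind_rows()
    out |>
      group_by(.data$pool) |>
      mutate(read_id = sprintf("%s_r%06d", .data$pool, row_number())) |>
      ungroup() |>
      select("pool", "read_id", "seq", "true_species", "provenance")
  })
}
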