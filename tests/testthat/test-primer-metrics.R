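mini_primer <- primer("mini.logo", "ACGAACGA")

make_sites <- function(acc, site_seq, mismatches = 0L, start = 0L) {
  tibble::tibble(accession = acc, primer = mini_primer$name, strand = "+",
                 start = start, end = start + nchar(site_seq),
                 mismatches = mismatches, three_prime_match = TRUE,
                 site_seq = site_seq)
}

test_that("position count matrices tally template bases per group", {
  sites <- make_sites(c("a1", "a2"), c("ACGAACGA", "ACGAACGA"))
  pcm <- build_pcm(mini_primer, sites, c(a1 = "g1", a2 = "g1"))
  at <- function(pos, base) pcm$count[pcm$position == pos & pcm$base == base]
  expect_equal(at(1, "A"), 2L)
  expect_equal(at(2, "C"), 2L)
  expect_equal(at(2, "A"), 0L)

  # divergent final base splits the last column
  sites2 <- make_sites(c("a1", "a2"), c("ACGAACGA", "ACGAACGT"))
  pcm2 <- build_pcm(mini_primer, sites2, c(a1 = "g1", a2 = "g1"))
  last <- pcm2[pcm2$position == 8, ]
  expect_equal(last$count[last$base == "A"], 1L)
  expect_equal(last$count[last$base == "T"], 1L)

  # degenerate template bases land in the 'other' row
  sites3 <- make_sites("a1", "ACGANCGA")
  pcm3 <- build_pcm(mini_primer, sites3, c(a1 = "g1"))
  expect_equal(pcm3$count[pcm3$position == 5 & pcm3$base == "other"], 1L)

  expect_error(build_pcm(mini_primer, make_sites("a1", "ACGA")), "length")
})

test_that("every PCM column sums to the group's sequence count", {
  withr::local_seed(41)
  accs <- sprintf("a%02d", 1:9)
  sites <- make_sites(accs,
                      vapply(1:9, function(i) random_seq(8, 0.15),
                             character(1)))
  grp <- stats::setNames(rep(c("g1", "g2", "g3"), each = 3), accs)
  pcm <- build_pcm(mini_primer, sites, grp)
  sums <- dplyr::summarise(dplyr::group_by(pcm, group, position),
                           s = sum(count), n = unique(n_sequences),
                           .groups = "drop")
  expect_true(all(sums$s == sums$n))
  expect_true(all(sums$n == 3L))
})

test_that("multi-site entries contribute one best site to the logo", {
  sites <- dplyr::bind_rows(
    make_sites("a1", "ACGAACGA", mismatches = 0L, start = 10L),
    make_sites("a1", "TTTTTTTT", mismatches = 4L, start = 2L),
    make_sites("a1", "ACGAACGT", mismatches = 0L, start = 30L))
  # lowest mismatch count wins, then leftmost: the site at start 10
  pcm <- build_pcm(mini_primer, sites, c(a1 = "g"))
  expect_equal(unique(pcm$n_sequences), 1L)
  expect_equal(pcm$count[pcm$position == 8 & pcm$base == "A"], 1L)
  expect_equal(pcm$count[pcm$position == 8 & pcm$base == "T"], 0L)
})

test_that("coverage table tallies site presence and strict amplification per group", {
  cfg <- synth_ref_config(n_target_species = 6, clade_b_species = 1,
                          offtarget_sizes = c("Hymenoptera" = 3,
                                              "Coleoptera" = 2),
                          seed = 42)
  sr <- synth_reference_set(cfg)
  pol <- match_policy(require_three_prime = FALSE)
  sites <- dplyr::bind_rows(
    find_binding_sites(sr$pair$forward, sr$refs, pol),
    find_binding_sites(sr$pair$reverse, sr$refs, pol))
  hits <- amplify(sr$pair, sr$refs, pol)
  cov <- coverage_table(sr$refs, sites, hits, sr$pair)

  culicid <- cov[cov$group == "Culicidae", ]
  expect_equal(culicid$n_total, 6L)
  expect_equal(culicid$n_strict_amplifiable, 6L)
  expect_equal(culicid$frac_strict_amplifiable, 1)
  # only the target group carries the forward 3' base
  off <- cov[cov$group != "Culicidae", ]
  expect_true(all(off$n_strict_amplifiable == 0L))
  expect_true(all(off$n_forward_3p_match == 0L))
  # but the sites themselves are there (reverse site is conserved)
  expect_true(all(off$n_both_sites == off$n_total))
  expect_true(all(cov$n_strict_amplifiable <= cov$n_both_sites))
  expect_true(all(cov$n_both_sites <= cov$n_total))

  # counts are invariant to entry order
  perm <- sample(nrow(sr$refs))
  cov2 <- coverage_table(sr$refs[perm, ], sites, hits, sr$pair)
  expect_equal(dplyr::arrange(cov, group), dplyr::arrange(cov2, group))

  # empty group: zero counts, NA fractions, no division error
  refs_plus <- dplyr::bind_rows(
    sr$refs, make_refs(c(zz = "ACGTACGTACGT"), species = "Ghost_sp",
                       group = "Lepidoptera"))
  cov3 <- coverage_table(refs_plus, sites, hits, sr$pair)
  lep <- cov3[cov3$group == "Lepidoptera", ]
  expect_equal(lep$n_total, 1L)
  hit_none <- coverage_table(make_refs(c(zz = "ACGT"), group = "empty"),
                             sites[0, ], hits[0, ], sr$pair)
  expect_equal(hit_none$n_strict_amplifiable, 0L)
})

test_that("resolution scores follow both stated conventions", {
  hits <- tibble::tibble(accession = c("a", "b", "c"),
                         species = c("sp1", "sp2", "sp3"),
                         insert = c("X", "X", "Y"))
  su <- resolution_score(hits)
  expect_equal(su$value, 1 / 3)
  expect_equal(su$n_resolved, 1L)
  lca <- resolution_score(hits, mode = "amplicon-lca")
  expect_equal(lca$value, 1 / 2)

  # all species mutually unique -> 1.0 under both modes
  uniq <- tibble::tibble(accession = letters[1:4],
                         species = paste0("sp", 1:4),
                         insert = c("I1", "I2", "I3", "I4"))
  expect_equal(resolution_score(uniq)$value, 1)
  expect_equal(resolution_score(uniq, mode = "amplicon-lca")$value, 1)

  # a single species can never conflict
  solo <- tibble::tibble(accession = c("a", "a2"), species = "sp1",
                         insert = c("I1", "I2"))
  expect_equal(resolution_score(solo)$value, 1)

  # species_of mapping form
  hits2 <- dplyr::select(hits, -species)
  expect_equal(resolution_score(hits2, c(a = "s1", b = "s2", c = "s3"))$value,
               1 / 3)
})

test_that("merging species labels never changes third-party resolution", {
  # sound core of the coarsening property: species not involved in a merge
  # keep their resolved status (their insert sharing is unchanged)
  withr::local_seed(43)
  for (i in 1:15) {
    n_sp <- sample(4:7, 1)
    hits <- tibble::tibble(
      accession = sprintf("a%02d", 1:12),
      species = sample(paste0("sp", 1:n_sp), 12, replace = TRUE),
      insert = sample(paste0("I", 1:6), 12, replace = TRUE))
    pair_to_merge <- sample(unique(hits$species), 2)
    resolved_of <- function(h) {
      pairs <- dplyr::distinct(h, species, insert)
      shared <- dplyr::filter(dplyr::count(pairs, insert), n > 1)$insert
      bad <- unique(pairs$species[pairs$insert %in% shared])
      setdiff(unique(pairs$species), bad)
    }
    before <- resolved_of(hits)
    merged <- dplyr::mutate(hits, species = ifelse(
      species %in% pair_to_merge, "sp_merged", species))
    after <- resolved_of(merged)
    third <- setdiff(unique(hits$species), pair_to_merge)
    expect_setequal(intersect(before, third), intersect(after, third))
  }
  # and a concrete decreasing case: merging pulls in a shared insert
  hits <- tibble::tibble(accession = c("a", "b", "c"),
                         species = c("spA", "spB", "spC"),
                         insert = c("X", "Y", "X"))
  expect_equal(resolution_score(hits)$value, 1 / 3)  # only spB resolved
  merged <- dplyr::mutate(hits, species = ifelse(species %in% c("spA", "spB"),
                                                 "spAB", species))
  expect_equal(resolution_score(merged)$value, 0)
})

test_that("shared-species restriction is a set intersection", {
  ha <- tibble::tibble(accession = 1:3, species = c("s1", "s2", "s3"),
                       insert = c("A", "B", "C"))
  hb <- tibble::tibble(accession = 4:6, species = c("s2", "s3", "s4"),
                       insert = c("B", "C", "D"))
  both <- shared_species_subset(ha, hb)
  expect_setequal(both$a$species, c("s2", "s3"))
  expect_setequal(both$b$species, c("s2", "s3"))

  disjoint <- shared_species_subset(
    ha, dplyr::mutate(hb, species = c("x", "y", "z")))
  expect_equal(nrow(disjoint$a), 0L)
  expect_equal(nrow(disjoint$b), 0L)

  same <- shared_species_subset(ha, ha)
  expect_identical(same$a, ha)
})

test_that("amplicon statistics use sample SD", {
  hits <- tibble::tibble(group = "g",
                         length = c(380L, 420L),
                         insert_length = c(341L, 381L),
                         insert = c("GGCC", "GGCC"),
                         gc = c(1, 1))
  st <- amplicon_stats(hits)
  expect_equal(st$length_mean, 400)
  expect_equal(st$length_sd, sqrt(sum((c(380, 420) - 400)^2) / 1),
               tolerance = 1e-12)
  expect_equal(round(st$length_sd, 2), 28.28)
  expect_equal(st$gc_mean, 1)

  same <- amplicon_stats(tibble::tibble(group = "g", length = c(400L, 400L),
                                        insert_length = c(361L, 361L),
                                        gc = c(0.5, 0.5)))
  expect_equal(same$length_mean, 400)
  expect_equal(same$length_sd, 0)
})
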