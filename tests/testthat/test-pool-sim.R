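test_that("the synthetic reference generator is deterministic under seed", {
  sr1 <- synth_reference_set(synth_ref_config(seed = 71))
  sr2 <- synth_reference_set(synth_ref_config(seed = 71))
  expect_identical(sr1$refs, sr2$refs)
  expect_identical(sr1$library, sr2$library)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference_set(sr1$refs, f1, tempfile())
  write_reference_set(sr2$refs, f2, tempfile())
  expect_identical(readLines(f1), readLines(f2))  # byte-identical FASTA
  sr3 <- synth_reference_set(synth_ref_config(seed = 72))
  expect_false(identical(sr1$refs$seq, sr3$refs$seq))
})

test_that("planted structure: strict 3' policy separates target from off-target", {
  sr <- synth_reference_set(synth_ref_config(seed = 73))
  strict <- amplify(sr$pair, sr$refs, match_policy())
  expect_setequal(unique(strict$group), "Culicidae")
  n_target <- sum(sr$refs$group == "Culicidae")
  expect_equal(dplyr::n_distinct(strict$accession), n_target)
  expect_equal(resolution_score(strict)$value, 1)

  # single target species -> trivially resolved
  sr1 <- synth_reference_set(synth_ref_config(n_target_species = 1,
                                              clade_b_species = 0,
                                              seed = 74))
  h1 <- amplify(sr1$pair, sr1$refs, match_policy())
  expect_equal(resolution_score(h1)$value, 1)
})

test_that("generated amplicons mirror the configured clade length regimes", {
  sr <- synth_reference_set(synth_ref_config(n_target_species = 40,
                                             clade_b_species = 10,
                                             seed = 75))
  hits <- amplify(sr$pair, sr$refs, match_policy())
  culicine <- hits[grepl("^Culicine", hits$species), ]
  anopheline <- hits[grepl("^Anopheline", hits$species), ]
  expect_equal(mean(culicine$insert_length), 383, tolerance = 0.02)
  expect_equal(mean(anopheline$insert_length), 432, tolerance = 0.03)
  expect_gt(sd(anopheline$insert_length), sd(culicine$insert_length))
  expect_equal(mean(hits$gc), 0.60, tolerance = 0.05)
})

test_that("true proportions follow volume x amplifiability x degradation", {
  design <- tibble::tibble(pool = "P", species = c("s1", "s2"),
                           volume_ul = c(10, 10))
  cfg <- pool_sim_config(design, depth = 100, seed = 76)
  tp <- true_proportions(cfg)
  expect_equal(tp$prop, c(0.5, 0.5))  # uniform under equal everything

  cfg2 <- pool_sim_config(
    design, specimens = specimen_models(c("s1", "s2"),
                                        amplifiability = c(2, 1)),
    depth = 100, seed = 76)
  expect_equal(true_proportions(cfg2)$prop, c(2 / 3, 1 / 3))

  # degradation is a further multiplicative loss
  cfg3 <- pool_sim_config(
    design, specimens = specimen_models(c("s1", "s2"),
                                        degradation = c(0.5, 1)),
    depth = 100, seed = 76)
  expect_equal(true_proportions(cfg3)$prop, c(1 / 3, 2 / 3))

  # 1:10 bycatch mix with no carryover: target mass share = 1/(1+10)
  cfg10 <- pool_sim_config(design, depth = 100, bycatch_dna_ratio = 10,
                           seed = 76)
  tp10 <- true_proportions(cfg10)
  expect_equal(sum(tp10$prop[tp10$provenance == "target"]), 1 / 11)
  expect_equal(sum(tp10$prop), 1)
  # dominant bycatch family carries the largest bycatch share
  by_fam <- tp10[tp10$provenance == "bycatch", ]
  expect_equal(by_fam$species[which.max(by_fam$prop)], "Chaoboridae")
})

test_that("simulated read counts behave at the depth extremes", {
  design <- tibble::tibble(pool = "P", species = c("s1", "s2", "s3"),
                           volume_ul = c(1, 2, 3))
  # N = 1 with no quality loss: exactly one read in one category
  one <- simulate_reads(pool_sim_config(design, depth = 1, quality_loss = 0,
                                        seed = 77))
  expect_equal(sum(one$reads$reads), 1L)
  # no bycatch configured -> no bycatch or contaminant categories
  expect_setequal(unique(one$provenance$provenance), "target")

  # law of large numbers: realized proportions near truth at N = 1e6
  big_cfg <- pool_sim_config(design, depth = 1e6, quality_loss = 0,
                             seed = 78)
  big <- simulate_reads(big_cfg)
  obs <- big$reads$reads / sum(big$reads$reads)
  expect_lt(max(abs(obs - true_proportions(big_cfg)$prop)), 0.005)

  # provenance tallies sum to the realized post-filter depth
  q <- simulate_reads(pool_sim_config(design, depth = 5000,
                                      quality_loss = 0.2, seed = 79))
  expect_equal(sum(q$provenance$reads), q$depth$realized_depth)
  expect_equal(q$depth$raw_depth, round(5000 / 0.8))

  # same seed -> identical counts
  r1 <- simulate_reads(pool_sim_config(design, depth = 5000, seed = 80))
  r2 <- simulate_reads(pool_sim_config(design, depth = 5000, seed = 80))
  expect_identical(r1$reads, r2$reads)
})

test_that("end-to-end recovery: Best Estimate tracks the amplifiability profile", {
  withr::local_seed(81)
  species <- sprintf("sp%02d", 1:17)
  amp <- exp(rnorm(17, 0, 0.7))
  design <- fresh_pool_design(species, n_pools = 4, seed = 82)
  cfg <- pool_sim_config(design,
                         specimens = specimen_models(species,
                                                     amplifiability = amp),
                         depth = 17000, seed = 83)
  run <- simulate_reads(cfg)
  norm <- normalize_by_volume(run$reads, design)
  be <- best_estimate(norm)
  truth <- tibble::tibble(species = species, value = amp / sum(amp))
  g <- glance(fit_regression(truth, be))
  expect_gt(g$r_squared, 0.95)
  expect_equal(g$slope, 1, tolerance = 0.15)
})

test_that("dropout frequencies are realistic for degraded, shallow pools", {
  # one strongly degraded stock at 2% of the pool volume, 200 replicate
  # pools at the shallow degraded-pool depth: dropout happens sometimes
  species <- sprintf("sp%02d", 1:17)
  vol <- c(2, rep(98 / 16, 16))
  design <- tidyr::expand_grid(pool = sprintf("R%03d", 1:200),
                               species = species) |>
    dplyr::mutate(volume_ul = rep(vol, 200))
  withr::local_seed(84)
  deg <- c(0.02, runif(16, 0.3, 1))
  cfg <- pool_sim_config(design,
                         specimens = specimen_models(species,
                                                     degradation = deg),
                         depth = 3400, quality_loss = 0.2, seed = 85)
  run <- simulate_reads(cfg)
  drops <- detect_dropouts(run$reads, design)
  expect_gt(sum(drops$species == "sp01"), 0)

  # fresh pools at full depth: a >= 5% species never drops out
  design_f <- tidyr::expand_grid(pool = sprintf("F%03d", 1:50),
                                 species = species) |>
    dplyr::mutate(volume_ul = rep(c(5, rep(95 / 16, 16)), 50))
  run_f <- simulate_reads(pool_sim_config(design_f, depth = 17000,
                                          seed = 86))
  expect_equal(nrow(detect_dropouts(run_f$reads, design_f)), 0L)
})

test_that("carryover contamination enriches the contaminant species", {
  species <- sprintf("sp%02d", 1:10)
  design <- tibble::tibble(pool = "P", species = species, volume_ul = 10)
  cfg <- pool_sim_config(design, depth = 5e4, bycatch_dna_ratio = 10,
                         carryover_fraction = 0.05,
                         contaminant_species = "sp03", seed = 87)
  run <- simulate_reads(cfg)
  reads <- run$reads[run$reads$species %in% species, ]
  share <- reads$reads / sum(reads$reads)
  names(share) <- reads$species
  # design expectation is uniform 1/10 of the target reads; carryover mass
  # (0.05 * 10 units) dwarfs sp03's design share
  expect_gt(share[["sp03"]], 2 * mean(share[names(share) != "sp03"]))
})
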