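# End-to-end pipeline: simulate -> amplify -> metrics -> assign -> quant,
# with a reproducibility manifest.

.known_pipeline_keys <- c("synth", "design", "sim", "policy")

#' Run the full demonstration pipeline
#'
#' Generates a synthetic reference set and variant library, predicts
#' amplicons for the configured primer pair, summarises coverage and
#' resolution, simulates pooled reads, assigns them by exact identity, and
#' quantifies abundance fidelity. All artifacts are written to `out_dir`
#' together with a `manifest.json` recording inputs, parameters, seed and
#' versions; a rerun from the same seed and config is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param config Named list (or path to a YAML file) with optional entries:
#'   `synth` (arguments to [synth_ref_config()]), `design` (arguments to
#'   [fresh_pool_design()]: `n_pools`, `vol_range`), `sim` (arguments to
#'   [pool_sim_config()]: `depth`, `bycatch_dna_ratio`, `carryover_fraction`,
#'   `quality_loss`, ...), `policy` (arguments to [match_policy()]).
#'   Unknown top-level keys are rejected.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = list(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config) %||% list()
  unknown <- setdiff(names(config), .known_pipeline_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  path <- function(f) file.path(out_dir, f)

  syn_args <- config$synth %||% list()
  if (!is.null(syn_args$primers)) {
    syn_args$pair <- primer_pair(
      primer("custom.F", syn_args$primers$forward),
      primer("custom.R", syn_args$primers$reverse))
    syn_args$primers <- NULL
  }
  syn_args$seed <- seed
  cfg <- do.call(synth_ref_config, syn_args)

  say("simulate: reference set + variant library")
  sr <- synth_reference_set(cfg)
  write_reference_set(sr$refs, path("refs.fa"), path("tax.tsv"))
  write_library(sr$library, path("library.fa"))

  say("amplify: in-silico PCR")
  policy <- do.call(match_policy, config$policy %||% list())
  sites <- bind_rows(find_binding_sites(sr$pair$forward, sr$refs, policy),
                     find_binding_sites(sr$pair$reverse, sr$refs, policy))
  hits <- amplify(sr$pair, sr$refs, policy)
  hits_out <- hits |>
    select("accession", "species", "group", strand = "orientation",
           "fwd_start", "fwd_mm", "fwd_3p", "rev_start", "rev_mm", "rev_3p",
           "length", "gc")
  readr::write_tsv(hits_out, path("hits.tsv"), progress = FALSE)
  amp <- Biostrings::DNAStringSet(hits$product)
  names(amp) <- sprintf("%s_%d_%d", hits$accession,
                        pmin(hits$fwd_start, hits$rev_start),
                        pmax(hits$fwd_end, hits$rev_end))
  Biostrings::writeXStringSet(amp, path("amplicons.fa"), width = 80L)

  say("metrics: coverage, logos, resolution")
  readr::write_tsv(coverage_table(sr$refs, sites, hits, sr$pair),
                   path("coverage.tsv"), progress = FALSE)
  grp <- stats::setNames(sr$refs$group, sr$refs$accession)
  pcm <- bind_rows(
    build_pcm(sr$pair$forward,
              filter(sites, .data$primer == sr$pair$forward$name), grp),
    build_pcm(sr$pair$reverse,
              filter(sites, .data$primer == sr$pair$reverse$name), grp))
  readr::write_tsv(pcm, path("pcm.tsv"), progress = FALSE)
  res <- bind_rows(resolution_score(hits, mode = "species-unique"),
                   resolution_score(hits, mode = "amplicon-lca"))
  readr::write_tsv(res, path("resolution.tsv"), progress = FALSE)

  say("simulate: pooled reads")
  des_args <- config$design %||% list()
  des_args$species <- unique(sr$library$species)
  des_args$seed <- seed
  design <- do.call(fresh_pool_design, des_args)
  sim_args <- config$sim %||% list()
  sim_args$design <- design
  sim_args$seed <- seed
  scfg <- do.call(pool_sim_config, sim_args)
  run <- simulate_reads(scfg)
  readr::write_tsv(design, path("design.tsv"), progress = FALSE)
  readr::write_tsv(run$reads, path("reads.tsv"), progress = FALSE)
  readr::write_tsv(run$truth, path("truth.tsv"), progress = FALSE)

  say("assign: exact-identity assignment")
  read_seqs <- expand_read_sequences(run, sr$library, seed = seed)
  assigned <- assign_reads(read_seqs, sr$library)
  readr::write_tsv(tally_assignments(assigned, by = "pool"),
                   path("assignment.tsv"), progress = FALSE)

  say("quant: normalization, Best Estimate, fidelity")
  target_reads <- run$reads |> semi_join(design, by = c("pool", "species"))
  norm <- normalize_by_volume(target_reads, design)
  be <- best_estimate(norm)
  fid <- pool_fidelity(norm, be)
  readr::write_tsv(norm, path("normalized.tsv"), progress = FALSE)
  readr::write_tsv(be, path("best_estimate.tsv"), progress = FALSE)
  readr::write_tsv(fid, path("fidelity.tsv"), progress = FALSE)
  dr <- detect_dropouts(run$reads, design)
  readr::write_tsv(dr, path("dropouts.tsv"), progress = FALSE)

  manifest <- list(
    seed = seed,
    config = config,
    parameters = list(
      primers = list(forward = sr$pair$forward$seq,
                     reverse = sr$pair$reverse$seq),
      policy = unclass(policy),
      depth = scfg$depth, quality_loss = scfg$quality_loss,
      bycatch_dna_ratio = scfg$bycatch_dna_ratio,
      carryover_fraction = scfg$carryover_fraction),
    versions = list(ampliscope = as.character(packageVersion("ampliscope")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  artifacts <- list.files(out_dir)
  invisible(stats::setNames(
    as.list(file.path(out_dir, artifacts)), artifacts))
}
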