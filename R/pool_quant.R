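# Abundance fidelity of pooled amplicon sequencing: volume normalization,
# Best Estimate profiles, OLS diagnostics, dropout.

#' Normalize read counts by input volume
#'
#' Converts raw per-species read counts into volume-corrected proportions:
#' `value_i = (reads_i / volume_i) / sum_j(reads_j / volume_j)`. Species in
#' the design with zero reads are kept at 0 (dropout is informative); species
#' with reads but no design volume are an error. Handles one pool or many
#' (normalization is within-pool).
#'
#' @param reads Tibble `pool`, `species`, `reads` (non-negative integers).
#' @param design Tibble `pool`, `species`, `volume_ul` (> 0 for every
#'   included species).
#' @return Tibble `pool`, `species`, `volume_ul`, `reads`, `norm_prop`; the
#'   `norm_prop` values sum to 1 within each pool.
#' @export
normalize_by_volume <- function(reads, design) {
  reads <- as_tibble(reads); design <- as_tibble(design)
  stopifnot(all(c("pool", "species", "reads") %in% names(reads)),
            all(c("pool", "species", "volume_ul") %in% names(design)),
            all(reads$reads >= 0), all(design$volume_ul > 0))
  orphan <- reads |>
    filter(.data$reads > 0) |>
    anti_join(design, by = c("pool", "species"))
  if (nrow(orphan)) {
    stop("species with reads but no design volume: ",
         paste(unique(paste0(orphan$pool, ":", orphan$species)),
               collapse = ", "), call. = FALSE)
  }
  out <- design |>
    left_join(reads, by = c("pool", "species")) |>
    mutate(reads = dplyr::coalesce(.data$reads, 0)) |>
    group_by(.data$pool) |>
    mutate(rate = .data$reads / .data$volume_ul,
           total = sum(.data$rate)) |>
    ungroup()
  if (any(out$total == 0)) {
    bad <- unique(out$pool[out$total == 0])
    stop("pool(s) with zero total reads: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out |>
    mutate(norm_prop = .data$rate / .data$total) |>
    select("pool", "species", "volume_ul", "reads", "norm_prop")
}

#' Best Estimate of per-species amplifiable contribution
#'
#' Averages volume-normalized proportions across replicate pools — an
#' estimate of the read share each stock DNA would contribute from equal
#' input volumes. A species absent from (dropped out of) a pool contributes
#' 0 for that pool, not a missing value.
#'
#' @param normalized Output of [normalize_by_volume()] covering two or more
#'   pools.
#' @param pools Optional character vector restricting which pools are
#'   averaged.
#' @return Tibble `species`, `value` (mean normalized proportion), `n_pools`.
#' @export
best_estimate <- function(normalized, pools = NULL) {
  tbl <- as_tibble(normalized)
  if (!is.null(pools)) tbl <- filter(tbl, .data$pool %in% pools)
  n_pools <- dplyr::n_distinct(tbl$pool)
  if (n_pools < 2L) stop("need at least two pools to average", call. = FALSE)
  tbl |>
    tidyr::complete(pool = unique(tbl$pool), species = unique(tbl$species),
                    fill = list(norm_prop = 0)) |>
    group_by(.data$species) |>
    summarise(value = sum(.data$norm_prop) / n_pools, .groups = "drop") |>
    mutate(n_pools = n_pools)
}

# Pull (species, value) out of a profile tibble: accepts best_estimate
# output (value), normalize_by_volume output (norm_prop), or any two-column
# species + single-numeric-column tibble.
.profile_values <- function(x, arg) {
  x <- as_tibble(x)
  if (!"species" %in% names(x)) {
    stop("'", arg, "' needs a species column", call. = FALSE)
  }
  vcol <- intersect(c("value", "norm_prop"), names(x))[1]
  if (is.na(vcol)) {
    num <- names(x)[vapply(x, is.numeric, logical(1))]
    if (length(num) != 1L) {
      stop("'", arg, "' must carry exactly one value column", call. = FALSE)
    }
    vcol <- num
  }
  if (anyDuplicated(x$species)) {
    stop("'", arg, "' has duplicated species; pass a single pool",
         call. = FALSE)
  }
  tibble(species = x$species, value = x[[vcol]])
}

#' Regress an observed profile on an expected one
#'
#' Ordinary least squares `y = a + b x` over the species shared by the two
#' profiles, with a two-sided Pearson correlation test. Under volume
#' normalization the expectation for a faithful pool is slope 1 and
#' intercept near 0. Significance is judged against a Bonferroni-adjusted
#' alpha when several regressions are run in one analysis.
#'
#' @param x Expected profile (e.g. [best_estimate()] output, or design
#'   proportions as a `species` + value tibble).
#' @param y Observed profile (one pool of [normalize_by_volume()] output).
#' @param exclude_species Species dropped before fitting (e.g. specimens
#'   suspected of carryover contamination).
#' @param m_tests Number of tests in the family (Bonferroni m; default 1).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `fidelity_fit` object; see [tidy()], [glance()],
#'   [autoplot.fidelity_fit()].
#' @export
fit_regression <- function(x, y, exclude_species = character(0),
                           m_tests = 1L, alpha = 0.05) {
  xv <- .profile_values(x, "x")
  yv <- .profile_values(y, "y")
  dat <- inner_join(xv, yv, by = "species", suffix = c("_x", "_y")) |>
    filter(!.data$species %in% exclude_species)
  if (nrow(dat) < 3L) {
    stop("need at least 3 shared species after exclusions", call. = FALSE)
  }
  if (stats::var(dat$value_x) == 0) {
    stop("zero variance in x; regression undefined", call. = FALSE)
  }
  fit <- lm(value_y ~ value_x, data = dat)
  ct <- cor.test(dat$value_x, dat$value_y, method = "pearson",
                 alternative = "two.sided")
  structure(list(model = fit, cor = ct, data = dat,
                 n = nrow(dat), m_tests = as.integer(m_tests),
                 alpha = alpha, alpha_adjusted = alpha / m_tests,
                 excluded = exclude_species),
            class = "fidelity_fit")
}

#' @export
print.fidelity_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fidelity_fit> n = %d species\n  slope = %.4f  intercept = %.4f\n  R^2 = %.4f  (Pearson r = %.4f, p = %.3g)\n  significant at Bonferroni-adjusted alpha %.4g: %s\n",
    g$n, g$slope, g$intercept, g$r_squared, g$pearson_r, g$p_value,
    g$alpha_adjusted, ifelse(g$significant, "yes", "no")))
  invisible(x)
}

#' Tidy a fidelity regression
#'
#' @param x A `fidelity_fit`.
#' @param ... Unused.
#' @return Coefficient-level tibble (`term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.fidelity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' Glance at a fidelity regression
#'
#' @param x A `fidelity_fit`.
#' @param ... Unused.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `pearson_r`,
#'   `p_value`, `n`, `m_tests`, `alpha_adjusted`, `significant`.
#' @export
glance.fidelity_fit <- function(x, ...) {
  cf <- coef(x$model)
  tibble(slope = unname(cf[2]), intercept = unname(cf[1]),
         r_squared = summary(x$model)$r.squared,
         pearson_r = unname(x$cor$estimate),
         p_value = x$cor$p.value, n = x$n, m_tests = x$m_tests,
         alpha_adjusted = x$alpha_adjusted,
         significant = x$cor$p.value < x$alpha_adjusted)
}

#' Fidelity regressions for many pools against one reference profile
#'
#' Convenience wrapper fitting [fit_regression()] for every pool in
#' `normalized` against `reference`, with Bonferroni m defaulting to the
#' number of pools tested.
#'
#' @param normalized [normalize_by_volume()] output (several pools).
#' @param reference Expected profile (e.g. [best_estimate()] output).
#' @param exclude_species,alpha Passed to [fit_regression()].
#' @param m_tests Bonferroni m; defaults to the number of pools.
#' @return One [glance()] row per pool, with a `pool` column.
#' @export
pool_fidelity <- function(normalized, reference,
                          exclude_species = character(0),
                          m_tests = NULL, alpha = 0.05) {
  pools <- unique(normalized$pool)
  m <- m_tests %||% length(pools)
  purrr::map(pools, function(p) {
    fit <- fit_regression(reference, filter(normalized, .data$pool == p),
                          exclude_species = exclude_species,
                          m_tests = m, alpha = alpha)
    mutate(glance(fit), pool = p, .before = 1)
  }) |> bind_rows()
}

#' Species present in the design but absent from the reads
#'
#' @param reads Tibble `pool`, `species`, `reads`.
#' @param design Tibble `pool`, `species`, `volume_ul`.
#' @return Tibble `pool`, `species`, `design_prop` (the dropped species'
#'   share of its pool's total volume); empty when nothing dropped out.
#' @export
detect_dropouts <- function(reads, design) {
  design |>
    group_by(.data$pool) |>
    mutate(design_prop = .data$volume_ul / sum(.data$volume_ul)) |>
    ungroup() |>
    left_join(select(as_tibble(reads), "pool", "species", "reads"),
              by = c("pool", "species")) |>
    mutate(reads = dplyr::coalesce(.data$reads, 0)) |>
    filter(.data$volume_ul > 0, .data$reads == 0) |>
    select("pool", "species", "design_prop")
}

#' Exact dropout probability at a given depth
#'
#' Probability that a species at true proportion `p` receives zero of `N`
#' multinomially sampled reads: the marginal of any one category is
#' binomial, so `P(zero reads) = (1 - p)^N`. Vectorized over both arguments.
#'
#' @param depth Number of (post-filter) reads `N >= 1`.
#' @param proportion True read proportion `0 < p <= 1`.
#' @return Numeric vector of probabilities.
#' @examples
#' dropout_probability(3050, 0.002)  # ~2.2e-3
#' dropout_probability(5000, 0.002)  # ~4.5e-5
#' @export
dropout_probability <- function(depth, proportion) {
  stopifnot(all(depth >= 1), all(proportion > 0), all(proportion <= 1))
  (1 - proportion)^depth
}
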