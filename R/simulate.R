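## Synthetic gypsum-drylands datasets: species pool with gypsophily
## indices, a dated phylogeny, an aridity/cover environment gradient and
## plot communities assembled by GI-dependent temperature filtering,
## with the seeded effects recorded as ground truth.

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate the dimensions of a gypsum drylands study design:
#' 89 plots, a regional pool of 111 perennial species of which 16 are
#' strict gypsophytes (GI = 5); mean maximum temperature of the hottest
#' month uniform on 30.8--34.5 degrees C, mean annual precipitation
#' uniform on 195--565 mm, total plant cover uniform on 11--52.2
#' percent.  Effect sizes control the seeded assembly signals: a
#' positive `beta_cmg_T` filters high-GI species into hot plots (raising
#' CMG and narrowing GR with temperature), `beta_div_T`/`beta_div_P`
#' increase abundance dominance (lowering inverse Simpson diversity)
#' towards hot and wet plots respectively, and `beta_rich_cover` makes
#' richness grow with plant cover.  `phylo_signal` (>= 0) concentrates
#' similar GI values within clades via a Brownian-threshold
#' re-assignment on the simulated tree.
#'
#' @param n_plots number of plots.
#' @param n_species_pool regional pool size.
#' @param n_gypsophytes number of strict gypsophytes (GI = 5) in the
#'   pool.
#' @param t_range,p_range,cover_range environmental ranges (degrees C,
#'   mm, percent).
#' @param beta_cmg_T GI-by-temperature occurrence filtering strength
#'   (log-odds scale per unit GI deviation at the hot end).
#' @param beta_div_T,beta_div_P dominance (lognormal sdlog) increase per
#'   unit of the scaled temperature / precipitation gradient.
#' @param beta_rich_cover relative richness increase from the barest to
#'   the densest plot.
#' @param base_richness expected plot richness at mid cover.
#' @param phylo_signal trait--tree association strength (0 = none).
#' @param tp_correlation target Pearson correlation between tmax and map
#'   (Gaussian copula; 0 = independent).
#' @param allow_gi1 include gypsum-avoiding (GI = 1) species in the pool
#'   (off by default: plots are actively selected gypsum soils).
#' @param seed default seed used by [generate_dataset()].
#' @return a validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_plots = 89L, n_species_pool = 111L,
                            n_gypsophytes = 16L,
                            t_range = c(30.8, 34.5),
                            p_range = c(195, 565),
                            cover_range = c(11, 52.2),
                            beta_cmg_T = 2, beta_div_T = 1.2,
                            beta_div_P = 0.8, beta_rich_cover = 0.6,
                            base_richness = 18L, phylo_signal = 0,
                            tp_correlation = 0, allow_gi1 = FALSE,
                            seed = NULL) {
  cfg <- list(n_plots = as.integer(n_plots),
              n_species_pool = as.integer(n_species_pool),
              n_gypsophytes = as.integer(n_gypsophytes),
              t_range = t_range, p_range = p_range,
              cover_range = cover_range,
              beta_cmg_T = beta_cmg_T, beta_div_T = beta_div_T,
              beta_div_P = beta_div_P, beta_rich_cover = beta_rich_cover,
              base_richness = as.integer(base_richness),
              phylo_signal = phylo_signal,
              tp_correlation = tp_correlation,
              allow_gi1 = isTRUE(allow_gi1), seed = seed)
  stopifnot(cfg$n_plots >= 1L, cfg$n_species_pool >= 2L,
            cfg$n_gypsophytes >= 0L, cfg$phylo_signal >= 0,
            diff(cfg$t_range) > 0, diff(cfg$p_range) > 0,
            diff(cfg$cover_range) > 0,
            abs(cfg$tp_correlation) < 1)
  if (cfg$n_gypsophytes > cfg$n_species_pool)
    stop("n_gypsophytes exceeds the pool size")
  class(cfg) <- "scenario_config"
  cfg
}

#' Generate a species pool with gypsophily indices
#'
#' Draws integer GI values: exactly `n_gypsophytes` species get GI = 5;
#' the rest are gypsovags with GI in 2--4 (plus GI = 1 when
#' `allow_gi1`).
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed.
#' @return a named GI vector (species `sp001`, `sp002`, ...).
#' @export
generate_pool <- function(cfg = scenario_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_species_pool
  ng <- cfg$n_gypsophytes
  vals <- if (cfg$allow_gi1) 1:4 else 2:4
  prb  <- if (cfg$allow_gi1) c(0.15, 0.40, 0.30, 0.15) else c(0.45, 0.35, 0.20)
  gi <- sample(vals, n - ng, replace = TRUE, prob = prb)
  gi <- c(gi, rep(5, ng))
  gi <- gi[sample.int(n)]
  stats::setNames(as.numeric(gi),
                  sprintf("sp%03d", seq_len(n)))
}

#' Simulate an ultrametric phylogeny over the pool
#'
#' Pure-birth (Yule) tree via [ape::rphylo()].  With
#' `phylo_signal > 0` the GI values are re-assigned by a
#' Brownian-threshold scheme: a Brownian trait is simulated on the tree,
#' blended with white noise in proportion
#' `h = phylo_signal / (1 + phylo_signal)`, and the pool's GI multiset
#' is re-dealt in the rank order of that latent value, so related
#' species share similar GI (class counts unchanged).
#'
#' @param pool named GI vector from [generate_pool()].
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed.
#' @return a list with `tree` (a `"phylo"` with the pool's species as
#'   tips) and `traits` (the possibly re-assigned GI vector).
#' @export
generate_tree <- function(pool, cfg = scenario_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pool)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- names(pool)
  traits <- pool
  if (cfg$phylo_signal > 0) {
    bm <- ape::rTraitCont(tr, model = "BM", sigma = 1)
    h <- cfg$phylo_signal / (1 + cfg$phylo_signal)
    latent <- sqrt(h) * as.numeric(scale(bm[names(pool)])) +
      sqrt(1 - h) * stats::rnorm(n)
    traits[order(latent)] <- sort(unname(pool))
  }
  list(tree = tr, traits = traits)
}

#' Generate the plot environment gradient
#'
#' Uniform marginals over the configured ranges; `tp_correlation != 0`
#' couples tmax and map through a Gaussian copula while preserving the
#' uniform marginals.  Cover is drawn independently.
#'
#' @inheritParams generate_tree
#' @return a data frame with columns `plot_id`, `tmax`, `map`, `cover`.
#' @export
generate_environment <- function(cfg = scenario_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_plots
  rho <- cfg$tp_correlation
  if (rho != 0) {
    # correlate the underlying normals; 2*sin(pi*rho/6) maps a target
    # Pearson correlation of the uniforms to the normal scale
    rho_n <- 2 * sin(pi * rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- rho_n * z1 + sqrt(1 - rho_n^2) * stats::rnorm(n)
    u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  } else {
    u1 <- stats::runif(n); u2 <- stats::runif(n)
  }
  data.frame(
    plot_id = sprintf("plot%03d", seq_len(n)),
    tmax  = cfg$t_range[1] + u1 * diff(cfg$t_range),
    map   = cfg$p_range[1] + u2 * diff(cfg$p_range),
    cover = stats::runif(n, cfg$cover_range[1], cfg$cover_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Assemble plot communities with seeded gradient effects
#'
#' For each plot with scaled temperature `t01` in `[0, 1]`: the target
#' richness is `base_richness * (1 - beta_rich_cover/2 +
#' beta_rich_cover * c01)` (cover-driven productivity); species are
#' drawn without replacement with occurrence weights
#' `exp(beta_cmg_T * (GI - 3.5) * t01)`, so the hot end filters for
#' high-GI specialists (CMG rises, GR narrows) while the cool end is
#' neutral; abundances are lognormal with
#' `sdlog = 1 + beta_div_T (t01 - 1/2) + beta_div_P (p01 - 1/2)`
#' (floored at 0.2) -- stronger dominance, hence lower inverse Simpson
#' diversity, towards hot and wet plots -- and are rescaled so each
#' plot's total abundance equals its cover value.
#'
#' @param pool named GI vector (use the one returned by
#'   [generate_tree()] when `phylo_signal > 0`).
#' @param env environment data frame from [generate_environment()].
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed.
#' @return a list with `community` (plot-by-species matrix) and `truth`
#'   (seeded effect sizes plus per-plot latent filtering intensities).
#' @export
generate_communities <- function(pool, env, cfg = scenario_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sp <- length(pool)
  gi <- unname(pool)
  t01 <- (env$tmax - cfg$t_range[1]) / diff(cfg$t_range)
  p01 <- (env$map - cfg$p_range[1]) / diff(cfg$p_range)
  c01 <- (env$cover - cfg$cover_range[1]) / diff(cfg$cover_range)
  t01 <- pmin(pmax(t01, 0), 1); p01 <- pmin(pmax(p01, 0), 1)
  c01 <- pmin(pmax(c01, 0), 1)

  s_target <- round(cfg$base_richness *
                      (1 - cfg$beta_rich_cover / 2 +
                         cfg$beta_rich_cover * c01))
  s_target <- pmin(pmax(s_target, 2L), n_sp)
  sigma <- pmax(0.2, 1 + cfg$beta_div_T * (t01 - 0.5) +
                  cfg$beta_div_P * (p01 - 0.5))

  m <- matrix(0, nrow(env), n_sp,
              dimnames = list(env$plot_id, names(pool)))
  resampled <- 0L
  for (k in seq_len(nrow(env))) {
    w <- exp(cfg$beta_cmg_T * (gi - 3.5) * t01[k])
    idx <- sample.int(n_sp, s_target[k], prob = w)
    ab <- stats::rlnorm(s_target[k], meanlog = 0, sdlog = sigma[k])
    while (sum(ab) <= 0) {           # pathological underflow guard
      resampled <- resampled + 1L
      ab <- stats::rlnorm(s_target[k], meanlog = 0, sdlog = sigma[k])
    }
    m[k, idx] <- ab * env$cover[k] / sum(ab)
  }
  truth <- list(
    beta_cmg_T = cfg$beta_cmg_T, beta_div_T = cfg$beta_div_T,
    beta_div_P = cfg$beta_div_P, beta_rich_cover = cfg$beta_rich_cover,
    expected_signs = list(CMG_tmax = "+", GR_tmax = "-",
                          invSimpson_tmax = "-", invSimpson_map = "-",
                          S_cover = "+"),
    t01 = t01, p01 = p01, sigma = sigma, s_target = s_target,
    n_resampled = resampled
  )
  list(community = m, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs pool, tree, environment and community generation under one seed
#' and cross-validates the result with [validate_dataset()].
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed (falls back to `cfg$seed`).
#' @return a list with `community`, `traits`, `tree`, `env`, `truth`,
#'   `config` and `data` (the validated `"gypsum_data"` object).
#' @export
generate_dataset <- function(cfg = scenario_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  pool <- generate_pool(cfg)
  tt <- generate_tree(pool, cfg)
  env <- generate_environment(cfg)
  com <- generate_communities(tt$traits, env, cfg)
  data <- validate_dataset(com$community, tt$traits, tt$tree, env)
  list(community = com$community, traits = tt$traits, tree = tt$tree,
       env = env, truth = com$truth, config = cfg, data = data)
}

#' Write a synthetic dataset as the four standard input files
#'
#' Writes `community.csv`, `traits.csv`, `tree.nwk`, `environment.csv`
#' and a `ground_truth.json` sidecar into `dir`; the files round-trip
#' through the package readers.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the five file paths.
#' @export
write_scenario <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("community.csv", "traits.csv", "tree.nwk",
                            "environment.csv", "ground_truth.json"))
  cm <- data.frame(plot = rownames(ds$community), ds$community,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_atomic(cm, paths[1L])
  write_atomic(data.frame(species_id = names(ds$traits),
                          GI = unname(ds$traits)), paths[2L])
  tmp <- tempfile(tmpdir = dir)
  ape::write.tree(ds$tree, file = tmp)
  file.rename(tmp, paths[3L])
  write_atomic(ds$env, paths[4L])
  tmp <- tempfile(tmpdir = dir)
  truth <- ds$truth
  truth$expected_signs <- as.list(truth$expected_signs)
  jsonlite::write_json(truth, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, paths[5L])
  invisible(paths)
}

## atomic CSV write: temp file in the target directory, then rename
write_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
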