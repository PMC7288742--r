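## Per-plot taxonomic and gypsophily (soil-affinity) metrics.
##
## All vector-level functions take one plot's abundances `x` and, where
## needed, the aligned gypsophily indices `gi`.  Zero-abundance species
## are dropped before any computation and relative abundances p_i are
## recomputed to sum to 1 (|sum(p) - 1| <= 1e-12 enforced).

drop_absent <- function(x, gi = NULL) {
  if (length(x) == 0L) stop("empty abundance vector")
  if (any(x < 0)) stop("negative abundance")
  keep <- x > 0
  if (!any(keep)) stop("no species with positive abundance")
  x <- x[keep]
  p <- x / sum(x)
  stopifnot(abs(sum(p) - 1) <= 1e-12)
  if (is.null(gi)) return(list(p = p))
  if (length(gi) != length(keep))
    stop("abundance and GI vectors differ in length")
  list(p = p, gi = gi[keep])
}

#' Species richness of one plot
#'
#' @param x numeric abundance vector for one plot (cover units); species
#'   with zero abundance are not counted.
#' @return integer count of species with positive abundance.
#' @export
richness <- function(x) {
  if (length(x) == 0L) stop("empty abundance vector")
  sum(x > 0)
}

#' Inverse Simpson diversity of one plot
#'
#' Effective species number `1 / sum(p_i^2)` over relative abundances
#' p_i of the species present; ranges from 1 (monoculture) to the
#' richness S (perfectly even assemblage).
#'
#' @inheritParams richness
#' @return a number in `[1, S]`.
#' @export
inverse_simpson <- function(x) {
  p <- drop_absent(x)$p
  1 / sum(p^2)
}

#' Gypsophily range (GR) of one assemblage
#'
#' `GR = max(GI) - min(GI)` over the species present: the span of the
#' soil-affinity niche axis occupied by the assemblage, analogous to
#' functional richness on a single trait.  Abundance-independent; ranges
#' from 0 (all species share one GI) to 4 on the full 1--5 GI scale
#' (3 when, as on actively selected gypsum plots, no GI = 1 species
#' occurs).
#'
#' @param gi numeric GI values of the species present in the plot
#'   (already restricted to positive-abundance species), each in
#'   `[1, 5]`.
#' @return a non-negative number.
#' @export
gypsophily_range <- function(gi) {
  if (length(gi) == 0L) stop("empty GI vector")
  max(gi) - min(gi)
}

#' Community mean gypsophily (CMG)
#'
#' Community weighted mean of the gypsophily index:
#' `CMG = sum(GI_i * p_i)` with p_i the relative abundance of species i.
#' Bounded by the smallest and largest GI present; equals 5 for a pure
#' gypsophyte assemblage.
#'
#' @param x numeric abundance vector for one plot.
#' @param gi GI values aligned to `x`.
#' @return a number between `min(gi)` and `max(gi)` of the species
#'   present.
#' @export
community_mean_gypsophily <- function(x, gi) {
  v <- drop_absent(x, gi)
  sum(v$gi * v$p)
}

#' Gypsophily diversity (GD, Rao quadratic entropy on GI)
#'
#' Rao quadratic diversity over the single gypsophily axis:
#' `GD = sum_{i,j} d_ij p_i p_j` with `d_ij = (GI_i - GI_j)^2`, summed
#' over all ordered species pairs (d_ii = 0).  Algebraically this equals
#' twice the abundance-weighted variance of GI; the implementation
#' evaluates the double sum directly.
#'
#' @inheritParams community_mean_gypsophily
#' @return a non-negative number; 0 iff all species present share one GI.
#' @export
gypsophily_diversity <- function(x, gi) {
  v <- drop_absent(x, gi)
  d <- outer(v$gi, v$gi, function(a, b) (a - b)^2)
  as.numeric(v$p %*% d %*% v$p)
}

## vectorized closed-form GD/CMG/GR over all plots for one GI assignment;
## used by the SES permutation loop (identity with the double sum is
## covered by the test suite)
metrics_all_plots <- function(P, present, gi) {
  cmg <- as.vector(P %*% gi)
  gd  <- pmax(0, 2 * (as.vector(P %*% gi^2) - cmg^2))
  gr  <- vapply(present, function(ix) {
    g <- gi[ix]
    max(g) - min(g)
  }, numeric(1L))
  list(GR = gr, CMG = cmg, GD = gd)
}

rel_abundance_matrix <- function(community) {
  sweep(community, 1L, rowSums(community), "/")
}

#' Per-plot taxonomic and gypsophily metrics
#'
#' Computes S, inverse Simpson, GR, CMG and GD for every plot of a
#' community matrix.
#'
#' @param community numeric plot-by-species matrix.
#' @param traits named GI vector covering all species in `community`.
#' @return a data frame with columns `plot_id`, `S`, `invSimpson`, `GR`,
#'   `CMG`, `GD`.
#' @export
community_metrics <- function(community, traits) {
  missing_tr <- setdiff(colnames(community), names(traits))
  if (length(missing_tr))
    stop("species without GI: ", paste(missing_tr, collapse = ", "))
  gi <- unname(traits[colnames(community)])
  out <- data.frame(
    plot_id    = rownames(community),
    S          = apply(community, 1L, richness),
    invSimpson = apply(community, 1L, inverse_simpson),
    GR         = apply(community, 1L, function(x) gypsophily_range(gi[x > 0])),
    CMG        = apply(community, 1L, community_mean_gypsophily, gi = gi),
    GD         = apply(community, 1L, gypsophily_diversity, gi = gi),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Standardized effect size of GR or GD under a trait-shuffle null
#'
#' Null model for the soil-affinity metrics: in each randomization the
#' assignment of GI values to species in the regional pool is permuted
#' (the community matrix stays fixed) and the metric is recomputed for
#' every plot.  `SES = (observed - null mean) / null sd`; a degenerate
#' null (sd = 0, e.g. a constant-GI pool) yields `NA` with a warning.
#'
#' @param community numeric plot-by-species matrix.
#' @param traits named GI vector covering the community's species.
#' @param metric `"GR"`, `"GD"` or both (default both).
#' @param n_rand number of randomizations (study default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param pool_traits optional named GI vector defining a regional pool
#'   larger than the community's species set; randomized GI values for
#'   the community are drawn from it without replacement.  Defaults to
#'   `traits` restricted to the community's species.
#' @return a data frame with columns `plot_id`, `metric`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `n_rand` (one row per plot and
#'   metric).
#' @export
ses_gypsophily <- function(community, traits, metric = c("GR", "GD"),
                           n_rand = 10000L, seed = NULL,
                           pool_traits = NULL) {
  metric <- match.arg(metric, several.ok = TRUE)
  stopifnot(n_rand >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sp <- colnames(community)
  gi_obs <- unname(traits[sp])
  if (anyNA(gi_obs)) stop("species without GI in trait table")
  pool <- if (is.null(pool_traits)) gi_obs else unname(pool_traits)
  if (length(pool) < length(sp))
    stop("regional pool smaller than the community's species set")

  P <- rel_abundance_matrix(community)
  present <- lapply(seq_len(nrow(community)),
                    function(i) which(community[i, ] > 0))
  obs <- metrics_all_plots(P, present, gi_obs)

  n_plot <- nrow(community)
  sums <- list(GR = numeric(n_plot), GD = numeric(n_plot))
  sq   <- list(GR = numeric(n_plot), GD = numeric(n_plot))
  for (b in seq_len(n_rand)) {
    gi_r <- sample(pool, length(sp))
    nl <- metrics_all_plots(P, present, gi_r)
    for (m in metric) {
      sums[[m]] <- sums[[m]] + nl[[m]]
      sq[[m]]   <- sq[[m]] + nl[[m]]^2
    }
  }

  res <- lapply(metric, function(m) {
    mu <- sums[[m]] / n_rand
    vv <- pmax(0, sq[[m]] / n_rand - mu^2) * n_rand / max(1, n_rand - 1)
    sdv <- sqrt(vv)
    ses <- ifelse(sdv > 0, (obs[[m]] - mu) / sdv, NA_real_)
    if (anyNA(ses))
      warning(sum(is.na(ses)), " plot(s) with degenerate ", m,
              " null (sd = 0): SES set to NA")
    data.frame(plot_id = rownames(community), metric = m,
               observed = obs[[m]], null_mean = mu, null_sd = sdv,
               ses = ses, n_rand = n_rand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
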