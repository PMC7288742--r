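## Phylogenetic structure of plot assemblages: patristic distances,
## the phylogenetic correlation matrix, PSV/PSR, MPD and NRI against an
## independent-swap null model.

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips
#' (cophenetic distances), in the tree's branch-length units.
#'
#' @param tree a rooted `"phylo"` object with branch lengths.
#' @return a symmetric species-by-species matrix with zero diagonal.
#' @export
phylo_distances <- function(tree) {
  validate_phylogeny(tree)
  if (!ape::is.rooted(tree)) stop("phylogeny must be rooted")
  ape::cophenetic.phylo(tree)
}

#' Phylogenetic correlation matrix
#'
#' `V_ab` is the shared root-to-tip branch length of tips a and b and
#' `C_ab = V_ab / sqrt(V_aa V_bb)` -- unit diagonal, 0 for tips split at
#' the root (a star phylogeny), approaching 1 for near-identical tips.
#' The normalization makes non-ultrametric trees admissible.
#'
#' @inheritParams phylo_distances
#' @return a symmetric correlation matrix over the tips.
#' @export
phylo_correlation <- function(tree) {
  validate_phylogeny(tree)
  if (!ape::is.rooted(tree)) stop("phylogeny must be rooted")
  V <- ape::vcv(tree)
  if (any(diag(V) <= 0))
    stop("tip(s) with zero root-to-tip distance: correlation undefined")
  stats::cov2cor(V)
}

#' Phylogenetic species variability (PSV)
#'
#' One minus the mean off-diagonal phylogenetic correlation among the
#' species of an assemblage.  PSV equals 1 when all species are
#' unrelated (a star phylogeny) and approaches 0 as they become more
#' related; it is undefined (`NA`) for singleton plots.
#'
#' @param C phylogenetic correlation matrix (see [phylo_correlation()]).
#' @param species character vector of the species present in the plot.
#' @return a number in `(0, 1]`, or `NA` if fewer than two species.
#' @export
psv <- function(C, species) {
  missing <- setdiff(species, rownames(C))
  if (length(missing))
    stop("species missing from correlation matrix: ",
         paste(missing, collapse = ", "))
  n <- length(species)
  if (n < 2L) return(NA_real_)
  Cs <- C[species, species]
  1 - (sum(Cs) - n) / (n * (n - 1))
}

#' Phylogenetic species richness (PSR)
#'
#' The product of PSV and species richness: richness discounted by
#' species relatedness, maximized at S on a star phylogeny.
#'
#' @param psv_value PSV of the assemblage (may be `NA`).
#' @param S species richness.
#' @return `psv_value * S` (`NA` propagates).
#' @export
psr <- function(psv_value, S) psv_value * S

#' Mean pairwise phylogenetic distance (MPD) of an assemblage
#'
#' Mean patristic distance over all unordered pairs of distinct species
#' present (presence-based, unweighted).
#'
#' @param species character vector of species present in the plot.
#' @param D patristic distance matrix (see [phylo_distances()]).
#' @return a non-negative number, or `NA` for singleton plots.
#' @export
mpd <- function(species, D) {
  missing <- setdiff(species, rownames(D))
  if (length(missing))
    stop("species missing from distance matrix: ",
         paste(missing, collapse = ", "))
  n <- length(species)
  if (n < 2L) return(NA_real_)
  Ds <- D[species, species]
  sum(Ds) / (n * (n - 1))
}

has_checkerboard <- function(m) {
  # a checkerboard exists iff some row pair has both a (1,0) and a (0,1)
  # column
  nr <- nrow(m)
  for (i in seq_len(nr - 1L)) {
    for (j in (i + 1L):nr) {
      d <- m[i, ] - m[j, ]
      if (any(d > 0) && any(d < 0)) return(TRUE)
    }
  }
  FALSE
}

#' Independent-swap randomization of a binary occupancy matrix
#'
#' Repeatedly draws random 2x2 submatrices and exchanges checkerboards
#' (`[[1,0],[0,1]]` or `[[0,1],[1,0]]`), which preserves every row sum
#' (plot richness) and column sum (species occupancy rate) exactly.  If
#' the matrix admits no checkerboard it is returned unchanged with a
#' warning.
#'
#' @param m binary (0/1) matrix with at least 2 rows and 2 columns.
#' @param iterations number of attempted swaps, or `"auto"` for 10 times
#'   the number of occupied cells.
#' @param seed optional integer seed.
#' @return the randomized matrix, with attribute `"swaps"` giving the
#'   number of successful swaps.
#' @export
independent_swap <- function(m, iterations = "auto", seed = NULL) {
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop("m must be a binary 0/1 matrix")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 plots and 2 species")
  if (identical(iterations, "auto")) iterations <- 10L * sum(m > 0)
  stopifnot(is.numeric(iterations), iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  storage.mode(m) <- "integer"
  out <- swap_engine(m, as.integer(iterations))
  dimnames(out) <- dimnames(m)
  if (attr(out, "swaps") == 0L && !has_checkerboard(m))
    warning("matrix admits no checkerboard; returned unchanged")
  out
}

#' Net relatedness index (NRI) per plot
#'
#' `NRI = -1 * (MPD - mean(MPD_rnd)) / sd(MPD_rnd)` where the null MPDs
#' come from independent-swap randomizations of the presence/absence
#' matrix (row and column sums fixed).  Positive NRI indicates
#' phylogenetic clustering, negative NRI higher-than-expected
#' phylogenetic diversity given the plot's richness.  Singleton plots
#' and plots with a zero null sd yield `NA`.
#'
#' @param community numeric plot-by-species matrix (only presence/absence
#'   is used).
#' @param tree rooted phylogeny with branch lengths covering the
#'   community's species.
#' @param n_rand number of null assemblages (study default 999).
#' @param swap_iterations attempted swaps per randomization, or `"auto"`
#'   (10 times the occupied cells); each randomization restarts from the
#'   observed matrix so null draws are independent.
#' @param seed optional integer seed.
#' @return a data frame with columns `plot_id`, `S`, `mpd_obs`,
#'   `mpd_null_mean`, `mpd_null_sd`, `nri`, plus attribute `"audit"`
#'   (n_rand, swap iterations, mean successful swaps, seed).
#' @export
nri <- function(community, tree, n_rand = 999L, swap_iterations = "auto",
                seed = NULL) {
  stopifnot(n_rand >= 1L)
  if (!is.null(seed)) set.seed(seed)
  missing_tip <- setdiff(colnames(community), tree$tip.label)
  if (length(missing_tip))
    stop("species missing from the phylogeny: ",
         paste(missing_tip, collapse = ", "))
  D <- phylo_distances(tree)[colnames(community), colnames(community)]
  pres <- (community > 0) * 1L
  storage.mode(pres) <- "integer"
  S <- rowSums(pres)

  # v' D v over ordered pairs; diag(D) = 0 so mpd = quad / (S (S - 1))
  mpd_of <- function(pm) {
    quad <- rowSums((pm %*% D) * pm)
    ifelse(S >= 2, quad / (S * (S - 1)), NA_real_)
  }
  mpd_obs <- mpd_of(pres)

  iters <- if (identical(swap_iterations, "auto")) 10L * sum(pres) else
    as.integer(swap_iterations)
  nsum <- numeric(nrow(pres)); nsq <- numeric(nrow(pres))
  swaps <- numeric(n_rand)
  for (b in seq_len(n_rand)) {
    pb <- swap_engine(pres, iters)
    swaps[b] <- attr(pb, "swaps")
    mb <- mpd_of(pb)
    nsum <- nsum + mb
    nsq <- nsq + mb^2
  }
  mu <- nsum / n_rand
  vv <- pmax(0, nsq / n_rand - mu^2) * n_rand / max(1, n_rand - 1)
  sdv <- sqrt(vv)
  nri_v <- ifelse(S >= 2 & sdv > 0, -1 * (mpd_obs - mu) / sdv, NA_real_)

  out <- data.frame(plot_id = rownames(community), S = as.integer(S),
                    mpd_obs = mpd_obs, mpd_null_mean = mu,
                    mpd_null_sd = sdv, nri = nri_v,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "audit") <- list(n_rand = n_rand, swap_iterations = iters,
                             mean_swaps = mean(swaps),
                             seed = if (is.null(seed)) NA else seed)
  out
}

#' Per-plot phylogenetic metrics (PSV, PSR, MPD, NRI)
#'
#' Convenience wrapper combining [psv()], [psr()], [mpd()] and [nri()]
#' for every plot of a community matrix.
#'
#' @inheritParams nri
#' @return a data frame with columns `plot_id`, `PSV`, `PSR`, `MPD`,
#'   `NRI` (NA for singleton plots), carrying the [nri()] audit
#'   attribute.
#' @export
phylo_metrics <- function(community, tree, n_rand = 999L,
                          swap_iterations = "auto", seed = NULL) {
  C <- phylo_correlation(tree)
  D <- phylo_distances(tree)
  sp_of <- lapply(seq_len(nrow(community)),
                  function(i) colnames(community)[community[i, ] > 0])
  S <- vapply(sp_of, length, 1L)
  psv_v <- vapply(sp_of, psv, numeric(1L), C = C)
  mpd_v <- vapply(sp_of, mpd, numeric(1L), D = D)
  nri_df <- nri(community, tree, n_rand = n_rand,
                swap_iterations = swap_iterations, seed = seed)
  out <- data.frame(plot_id = rownames(community),
                    PSV = psv_v, PSR = psr(psv_v, S), MPD = mpd_v,
                    NRI = nri_df$nri, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "audit") <- attr(nri_df, "audit")
  out
}
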