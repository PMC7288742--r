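# Independent oracles and fixture builders used across the suite.

# closed-form Rao identity: GD = 2 * abundance-weighted variance of GI
gd_weighted_var <- function(x, gi) {
  keep <- x > 0
  p <- x[keep] / sum(x[keep])
  g <- gi[keep]
  m <- sum(p * g)
  2 * sum(p * (g - m)^2)
}

# brute-force MPD: mean patristic distance over all unordered pairs
mpd_brute <- function(species, D) {
  if (length(species) < 2L) return(NA_real_)
  pairs <- utils::combn(species, 2L)
  mean(apply(pairs, 2L, function(pr) D[pr[1L], pr[2L]]))
}

# all permutations of a vector (for exhaustive trait-shuffle nulls)
all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# star phylogeny: n tips attached directly to the root, branch length len
star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr$root.edge <- 0   # explicit root: the basal polytomy is intentional
  tr
}

# small community fixture on decimal-exact abundances
toy_community <- function() {
  m <- matrix(c(1, 2, 0, 0.5,
                0, 0, 3, 1.25,
                2, 0, 1, 0),
              nrow = 3L, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"),
                              c("spA", "spB", "spC", "spD")))
  m
}

toy_traits <- function() c(spA = 5, spB = 2, spC = 3, spD = 4)

# random community matrix over a species pool, every plot non-empty
random_community <- function(n_plot, n_sp, fill = 0.3) {
  m <- matrix(rbinom(n_plot * n_sp, 1L, fill) * round(runif(n_plot * n_sp, 0.1, 9), 1),
              n_plot, n_sp,
              dimnames = list(sprintf("p%02d", seq_len(n_plot)),
                              sprintf("s%02d", seq_len(n_sp))))
  for (i in seq_len(n_plot))
    if (all(m[i, ] == 0)) m[i, sample.int(n_sp, 2L)] <- c(1, 2)
  m
}

write_env_csv <- function(env, path) {
  utils::write.csv(env, path, row.names = FALSE)
  path
}
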