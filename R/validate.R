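#' Cross-link and validate the four input artifacts
#'
#' Checks that every species in the community matrix has a gypsophily
#' index and a tip in the phylogeny, and that every plot has an
#' environment row; drops phylogeny tips and trait entries not used by
#' the community (the regional pool is the community's species set plus
#' any extra trait-table species when `pool = "traits"`).
#'
#' @param community numeric plot-by-species matrix
#'   (see [read_community_matrix()]).
#' @param traits named numeric GI vector (see [read_trait_table()]).
#' @param tree a `"phylo"` phylogeny with branch lengths, or `NULL` to
#'   run a taxonomic/functional-only analysis.
#' @param env environment data frame (see [read_environment_table()]).
#' @param cover_units passed to cover validation: `"percent"` or
#'   `"fraction"` (fractions are rescaled to percent).
#' @param pool species pool for trait null models: `"community"` (species
#'   occurring in the matrix, the default) or `"traits"` (every species in
#'   the trait table).
#' @return an object of class `"gypsum_data"`: a list with elements
#'   `community`, `traits`, `tree`, `env`, `pool_traits` and `summary`
#'   (n plots, n species, n strict gypsophytes with GI = 5).
#' @export
validate_dataset <- function(community, traits, tree = NULL, env = NULL,
                             cover_units = c("percent", "fraction"),
                             pool = c("community", "traits")) {
  cover_units <- match.arg(cover_units)
  pool <- match.arg(pool)
  if (!is.matrix(community) || !is.numeric(community))
    stop("community must be a numeric matrix")
  if (is.null(rownames(community)) || is.null(colnames(community)))
    stop("community matrix needs plot row names and species column names")
  if (any(community < 0)) stop("negative abundance in community matrix")
  empty <- rownames(community)[rowSums(community) <= 0]
  if (length(empty))
    stop("plot(s) with all-zero abundances: ", paste(empty, collapse = ", "))

  sp <- colnames(community)
  missing_tr <- setdiff(sp, names(traits))
  if (length(missing_tr))
    stop("species without a GI value: ", paste(missing_tr, collapse = ", "))
  if (any(traits < 1 | traits > 5)) stop("GI values must lie in [1, 5]")

  if (!is.null(tree)) {
    validate_phylogeny(tree)
    missing_tip <- setdiff(sp, tree$tip.label)
    if (length(missing_tip))
      stop("species missing from the phylogeny: ",
           paste(missing_tip, collapse = ", "))
    extra <- setdiff(tree$tip.label, sp)
    if (length(extra)) tree <- ape::drop.tip(tree, extra)
  }

  if (!is.null(env)) {
    if (!all(c("plot_id", "tmax", "map", "cover") %in% colnames(env)))
      stop("env must have columns plot_id, tmax, map, cover")
    if (cover_units == "fraction") env$cover <- env$cover * 100
    if (any(env$cover < 0 | env$cover > 100))
      stop("cover outside [0, 100] percent")
    missing_env <- setdiff(rownames(community), env$plot_id)
    if (length(missing_env))
      stop("plot(s) without environment data: ",
           paste(missing_env, collapse = ", "))
    env <- env[match(rownames(community), env$plot_id), , drop = FALSE]
    rownames(env) <- NULL
  }

  pool_traits <- if (pool == "traits") traits else traits[sp]
  out <- structure(
    list(
      community   = community,
      traits      = traits[sp],
      pool_traits = pool_traits,
      tree        = tree,
      env         = env,
      summary     = c(n_plots       = nrow(community),
                      n_species     = ncol(community),
                      n_gypsophytes = sum(traits[sp] == 5))
    ),
    class = "gypsum_data"
  )
  out
}

#' @export
print.gypsum_data <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Linked gypsum community dataset: %d plots, %d species, %d gypsophytes (GI = 5)\n",
              s[["n_plots"]], s[["n_species"]], s[["n_gypsophytes"]]))
  cat(sprintf("  phylogeny: %s | environment: %s\n",
              if (is.null(x$tree)) "absent" else
                sprintf("%d tips", length(x$tree$tip.label)),
              if (is.null(x$env)) "absent" else
                sprintf("tmax %.1f-%.1f degC, map %.0f-%.0f mm, cover %.1f-%.1f%%",
                        min(x$env$tmax), max(x$env$tmax),
                        min(x$env$map), max(x$env$map),
                        min(x$env$cover), max(x$env$cover))))
  invisible(x)
}
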