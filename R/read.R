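#' Read a plot-by-species community matrix from CSV
#'
#' The file must have a header row; the first column holds plot
#' identifiers and every remaining column is one species.  Cells are
#' non-negative abundances in cover units (raw transect lengths, percent
#' cover or proportions -- relative abundances are always recomputed
#' internally).  Blank cells are read as 0 (absence).
#'
#' @param path path to a CSV file (comma-separated, UTF-8, decimal point).
#' @return a numeric matrix with plot ids as row names and species ids as
#'   column names.
#' @seealso [read_trait_table()], [read_environment_table()],
#'   [read_phylogeny()], [validate_dataset()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plot,spA,spB,spC", "p1,1,2,0", "p2,0,0,3"), f)
#' read_community_matrix(f)
read_community_matrix <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("community matrix needs a plot id column plus at least one species")
  plots <- as.character(raw[[1L]])
  species <- colnames(raw)[-1L]
  dup_p <- plots[duplicated(plots)]
  if (length(dup_p))
    stop("duplicated plot id(s): ", paste(unique(dup_p), collapse = ", "))
  dup_s <- species[duplicated(species)]
  if (length(dup_s))
    stop("duplicated species column(s): ", paste(unique(dup_s), collapse = ", "))
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m) && !anyNA(raw[, -1L]))
      stop("non-numeric abundance values in community matrix")
  }
  m[is.na(m)] <- 0           # blank cells are absences
  dimnames(m) <- list(plots, species)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop(sprintf("negative abundance %g at plot '%s', species '%s'",
                 m[i[1L], i[2L]], plots[i[1L]], species[i[2L]]))
  }
  empty <- rownames(m)[rowSums(m) <= 0]
  if (length(empty))
    stop("plot(s) with no positive abundance: ", paste(empty, collapse = ", "))
  m
}

#' Read a species gypsophily trait table from CSV
#'
#' Two columns: species id and the gypsophily index GI, an ordinal
#' soil-affinity score from 1 (avoids gypsum soils) to 5 (strict
#' gypsophyte).  Real-valued GI inside \[1, 5\] is accepted.
#'
#' @param path path to a CSV file with columns `species_id, GI` (any
#'   header names; the first two columns are used).
#' @return a named numeric vector of GI values keyed by species id.
#' @export
read_trait_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("trait table needs columns: species_id, GI")
  sp <- as.character(raw[[1L]])
  gi <- as.numeric(raw[[2L]])
  dup <- sp[duplicated(sp)]
  if (length(dup))
    stop("duplicated species in trait table: ", paste(unique(dup), collapse = ", "))
  if (anyNA(gi)) stop("non-numeric GI value(s) in trait table")
  out_of_range <- sp[gi < 1 | gi > 5]
  if (length(out_of_range))
    stop("GI outside [1, 5] for: ", paste(out_of_range, collapse = ", "))
  stats::setNames(gi, sp)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Branch lengths are required (patristic distances are undefined without
#' them) and must be non-negative; tip labels must be unique.  Parsing is
#' delegated to [ape::read.tree()].
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `"phylo"` object.
#' @export
read_phylogeny <- function(path) {
  stopifnot(file.exists(path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_phylogeny(tr)
  tr
}

## shared checks, also applied to user-supplied in-memory trees
validate_phylogeny <- function(tr) {
  if (!inherits(tr, "phylo")) stop("phylogeny must be a 'phylo' object")
  if (is.null(tr$edge.length))
    stop("phylogeny has no branch lengths; patristic distances are undefined")
  if (any(tr$edge.length < 0)) stop("negative branch length in phylogeny")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("duplicated tip label(s): ", paste(unique(dup), collapse = ", "))
  invisible(tr)
}

#' Read a plot environment table from CSV
#'
#' One row per plot with the GLM predictors: mean maximum temperature of
#' the hottest month (`tmax`, degrees C), mean annual precipitation
#' (`map`, mm) and total perennial plant cover (`cover`).  Column names
#' are matched case-insensitively (`plot`/`plot_id`, `tmax`/`T`,
#' `map`/`P`/`precipitation`, `cover`).
#'
#' @param path path to a CSV file.
#' @param cover_units `"percent"` (0--100, the default) or `"fraction"`
#'   (0--1, rescaled to percent on read).
#' @return a data frame with columns `plot_id`, `tmax`, `map`, `cover`.
#' @export
read_environment_table <- function(path, cover_units = c("percent", "fraction")) {
  stopifnot(file.exists(path))
  cover_units <- match.arg(cover_units)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(colnames(raw))
  pick <- function(cands, what) {
    j <- which(nm %in% cands)[1L]
    if (is.na(j)) stop("environment table lacks a '", what, "' column")
    raw[[j]]
  }
  env <- data.frame(
    plot_id = as.character(pick(c("plot", "plot_id", "site", "id"), "plot id")),
    tmax    = as.numeric(pick(c("tmax", "t", "temperature"), "tmax")),
    map     = as.numeric(pick(c("map", "p", "precipitation", "prec"), "map")),
    cover   = as.numeric(pick(c("cover", "total_cover"), "cover")),
    stringsAsFactors = FALSE
  )
  dup <- env$plot_id[duplicated(env$plot_id)]
  if (length(dup))
    stop("duplicated plot id(s) in environment table: ",
         paste(unique(dup), collapse = ", "))
  if (any(!is.finite(env$tmax)) || any(!is.finite(env$map)))
    stop("non-finite tmax or map in environment table")
  if (cover_units == "fraction") env$cover <- env$cover * 100
  if (any(env$cover < 0 | env$cover > 100))
    stop("cover outside [0, 100] percent (is cover_units set correctly?)")
  env
}
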