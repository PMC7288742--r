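#' Fit the full gypsum community-assembly analysis
#'
#' End-to-end analysis of a gypsum plant community dataset: validates and
#' cross-links the inputs, computes per-plot taxonomic (S, inverse
#' Simpson), gypsophily (GR, CMG, GD plus trait-shuffle SES of GR and
#' GD) and phylogenetic (PSV, PSR, MPD, NRI with an independent-swap
#' null) metrics, checks predictor collinearity, and fits the per-metric
#' GLMs on `tmax * map + cover` with Type-II analysis-of-deviance
#' chi-square tests.
#'
#' @param community plot-by-species abundance matrix, or a path to its
#'   CSV file.
#' @param traits named GI vector, or a path to a trait CSV.
#' @param tree a `"phylo"` phylogeny, a Newick file path, or `NULL` to
#'   skip the phylogenetic metrics.
#' @param env environment data frame, or a path to its CSV file.
#' @param n_rand_trait randomizations for the GR/GD trait-shuffle SES
#'   (study default 10000).
#' @param n_rand_phylo independent-swap randomizations for NRI (study
#'   default 999).
#' @param swap_iterations attempted swaps per null assemblage, or
#'   `"auto"`.
#' @param seed integer seed governing both null models.
#' @param center_predictors mean-center tmax and map before forming the
#'   GLM interaction.
#' @param cover_units `"percent"` or `"fraction"`.
#' @param pool regional pool for the trait null: `"community"` or
#'   `"traits"` (see [validate_dataset()]).
#' @return an object of class `"gypsum_assembly"`: a list with elements
#'   `data` (the validated dataset), `metrics` (per-plot metric table),
#'   `collinearity`, `models` (named list of glm fits), `report` (the
#'   stacked Type-II deviance table), `config` and `audit`.
#' @seealso [summary.gypsum_assembly()], [generate_dataset()],
#'   [run_full_analysis()]
#' @export
#' @examples
#' ds <- generate_dataset(scenario_config(n_plots = 20, n_species_pool = 30,
#'                                        n_gypsophytes = 5), seed = 1)
#' fit <- gypsum_assembly(ds$community, ds$traits, ds$tree, ds$env,
#'                        n_rand_trait = 50, n_rand_phylo = 19, seed = 1)
#' fit
gypsum_assembly <- function(community, traits, tree = NULL, env,
                            n_rand_trait = 10000L, n_rand_phylo = 999L,
                            swap_iterations = "auto", seed = NULL,
                            center_predictors = FALSE,
                            cover_units = c("percent", "fraction"),
                            pool = c("community", "traits")) {
  cover_units <- match.arg(cover_units)
  pool <- match.arg(pool)
  if (is.character(community)) community <- read_community_matrix(community)
  if (is.character(traits)) traits <- read_trait_table(traits)
  if (is.character(tree)) tree <- read_phylogeny(tree)
  if (is.character(env)) {
    env <- read_environment_table(env, cover_units)
    cover_units <- "percent"        # already rescaled on read
  }
  data <- validate_dataset(community, traits, tree, env,
                           cover_units = cover_units, pool = pool)

  if (!is.null(seed)) set.seed(seed)
  seed_trait <- sample.int(.Machine$integer.max - 1L, 1L)
  seed_phylo <- sample.int(.Machine$integer.max - 1L, 1L)

  metrics <- community_metrics(data$community, data$traits)
  ses <- ses_gypsophily(data$community, data$traits,
                        metric = c("GR", "GD"), n_rand = n_rand_trait,
                        seed = seed_trait, pool_traits = data$pool_traits)
  metrics$SES_GR <- ses$ses[ses$metric == "GR"]
  metrics$SES_GD <- ses$ses[ses$metric == "GD"]

  audit <- list(seed = if (is.null(seed)) NA else seed,
                n_rand_trait = n_rand_trait,
                n_plots_singleton = sum(metrics$S < 2))
  if (!is.null(data$tree)) {
    ph <- phylo_metrics(data$community, data$tree, n_rand = n_rand_phylo,
                        swap_iterations = swap_iterations,
                        seed = seed_phylo)
    metrics <- cbind(metrics, ph[, c("PSV", "PSR", "MPD", "NRI")])
    audit$phylo_null <- attr(ph, "audit")
  }

  coll <- collinearity_check(data$env)
  gm <- gradient_models(metrics, data$env, center = center_predictors)
  audit$n_dropped <- vapply(gm$fits, function(f) attr(f, "n_dropped"), 1L)

  structure(
    list(data = data, metrics = metrics, collinearity = coll,
         models = gm$fits, report = gm$report,
         config = list(n_rand_trait = n_rand_trait,
                       n_rand_phylo = n_rand_phylo,
                       swap_iterations = swap_iterations,
                       center_predictors = center_predictors,
                       pool = pool, seed = seed),
         audit = audit),
    class = "gypsum_assembly"
  )
}

#' @export
print.gypsum_assembly <- function(x, ...) {
  s <- x$data$summary
  cat(sprintf("Gypsum community assembly analysis: %d plots, %d species, %d gypsophytes\n",
              s[["n_plots"]], s[["n_species"]], s[["n_gypsophytes"]]))
  cat(sprintf("tmax-map collinearity: r = %.3f (t = %.2f, P = %.3g)\n",
              x$collinearity$r, x$collinearity$t, x$collinearity$p_value))
  sig <- x$report[x$report$stars != "ns", , drop = FALSE]
  if (nrow(sig)) {
    cat("Significant gradient terms (Type-II scaled-deviance chi-square):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %-10s ~ %-9s (%s) chi2 = %5.1f %s\n", sig$response[i],
                  sig$term[i], sig$sign[i], sig$chi_square[i], sig$stars[i]))
  } else cat("No significant gradient terms.\n")
  invisible(x)
}

#' Summarize a fitted gypsum assembly analysis
#'
#' @param object a `"gypsum_assembly"` object.
#' @param ... unused.
#' @return the object, invisibly, after printing the per-plot metric
#'   ranges, the collinearity check and the full deviance report.
#' @export
summary.gypsum_assembly <- function(object, ...) {
  print(object)
  num <- object$metrics[, setdiff(colnames(object$metrics), "plot_id")]
  rng <- t(vapply(num, function(v)
    c(min = suppressWarnings(min(v, na.rm = TRUE)),
      mean = mean(v, na.rm = TRUE),
      max = suppressWarnings(max(v, na.rm = TRUE))), numeric(3L)))
  cat("\nPer-plot metric ranges:\n")
  print(round(rng, 3))
  cat("\nAnalysis of deviance (all terms):\n")
  rep <- object$report
  rep$chi_square <- round(rep$chi_square, 2)
  rep$p_value <- signif(rep$p_value, 3)
  rep$dispersion <- round(rep$dispersion, 3)
  print(rep, row.names = FALSE)
  invisible(object)
}

#' @export
coef.gypsum_assembly <- function(object, ...) {
  t(vapply(object$models, stats::coef,
           numeric(length(stats::coef(object$models[[1L]])))))
}

#' Predict one metric's GLM from a fitted analysis
#'
#' @param object a `"gypsum_assembly"` object.
#' @param response which metric's model to use (e.g. `"CMG"`).
#' @param newdata optional data frame with `tmax`, `map`, `cover`.
#' @param type passed to [stats::predict.glm()] (default response
#'   scale).
#' @param ... passed on to [stats::predict.glm()].
#' @return predicted values.
#' @export
predict.gypsum_assembly <- function(object, response = "CMG",
                                    newdata = NULL, type = "response",
                                    ...) {
  fit <- object$models[[response]]
  if (is.null(fit)) stop("no fitted model for response '", response, "'")
  if (is.null(newdata)) stats::predict(fit, type = type, ...)
  else stats::predict(fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.gypsum_assembly <- function(object, response = "CMG",
                                      type = "deviance", ...) {
  fit <- object$models[[response]]
  if (is.null(fit)) stop("no fitted model for response '", response, "'")
  stats::residuals(fit, type = type, ...)
}

#' Plot metric--gradient relationships
#'
#' Scatter plots of selected per-plot metrics against the temperature
#' gradient with the fitted GLM curve (at mean precipitation and cover)
#' overlaid.
#'
#' @param x a `"gypsum_assembly"` object.
#' @param responses metric columns to draw (default the four headline
#'   metrics).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.gypsum_assembly <- function(x, responses = c("invSimpson", "GR",
                                                  "CMG", "NRI"), ...) {
  responses <- intersect(responses, colnames(x$metrics))
  responses <- responses[vapply(responses,
                                function(r) !is.null(x$models[[r]]), TRUE)]
  if (!length(responses)) stop("no fitted responses to plot")
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(responses)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  env <- x$data$env
  for (r in responses) {
    graphics::plot(env$tmax, x$metrics[[r]], xlab = "tmax (degC)",
                   ylab = r, main = r, pch = 19,
                   col = "grey30", ...)
    tg <- seq(min(env$tmax), max(env$tmax), length.out = 80)
    nd <- data.frame(tmax = tg, map = mean(env$map),
                     cover = mean(env$cover))
    graphics::lines(tg, stats::predict(x$models[[r]], newdata = nd,
                                       type = "response"), lwd = 2)
  }
  invisible(x)
}

#' Run the full pipeline and write its outputs
#'
#' Reads (or accepts) the four input artifacts, runs
#' [gypsum_assembly()], and writes `metrics.csv` (one row per plot, all
#' metric columns), `model_report.csv` (the Type-II deviance report) and
#' `audit.log` into `outdir`.  Writes are atomic (temp file, then
#' rename), so no partial output is left on failure.
#'
#' @inheritParams gypsum_assembly
#' @param outdir output directory (created if needed).
#' @param ... further arguments passed to [gypsum_assembly()].
#' @return the fitted `"gypsum_assembly"` object, invisibly.
#' @export
run_full_analysis <- function(community, traits, tree = NULL, env,
                              outdir, ...) {
  fit <- gypsum_assembly(community, traits, tree, env, ...)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_atomic(fit$metrics, file.path(outdir, "metrics.csv"))
  write_atomic(fit$report, file.path(outdir, "model_report.csv"))
  tmp <- tempfile(tmpdir = outdir)
  writeLines(c(
    sprintf("gypsocom %s | R %s", as.character(utils::packageVersion("gypsocom")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("plots=%d species=%d gypsophytes=%d",
            fit$data$summary[["n_plots"]], fit$data$summary[["n_species"]],
            fit$data$summary[["n_gypsophytes"]]),
    sprintf("seed=%s n_rand_trait=%d n_rand_phylo=%d",
            as.character(fit$config$seed), fit$config$n_rand_trait,
            fit$config$n_rand_phylo),
    sprintf("collinearity r=%.4f t=%.3f p=%.4f", fit$collinearity$r,
            fit$collinearity$t, fit$collinearity$p_value),
    sprintf("singleton plots (NA phylo metrics): %d",
            fit$audit$n_plots_singleton),
    sprintf("NA responses dropped per model: %s",
            paste(names(fit$audit$n_dropped), fit$audit$n_dropped,
                  sep = "=", collapse = " ")),
    if (!is.null(fit$audit$phylo_null))
      sprintf("phylo null: n_rand=%d swap_iterations=%d mean_swaps=%.1f",
              fit$audit$phylo_null$n_rand,
              fit$audit$phylo_null$swap_iterations,
              fit$audit$phylo_null$mean_swaps)
  ), tmp)
  file.rename(tmp, file.path(outdir, "audit.log"))
  invisible(fit)
}
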