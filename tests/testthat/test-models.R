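make_env <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(plot_id = sprintf("p%03d", 1:n),
             tmax = runif(n, 30.8, 34.5),
             map = runif(n, 195, 565),
             cover = runif(n, 11, 52.2))
}

test_that("the default model table assigns the study families and links", {
  tab <- default_model_table()
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$family[tab$response == "S"], "poisson")
  expect_equal(tab$link[tab$response == "S"], "log")
  expect_equal(tab$family[tab$response == "CMG"], "quasipoisson")
  expect_equal(tab$link[tab$response == "CMG"], "log")
  gaussians <- c("invSimpson", "GR", "GD", "PSR", "PSV", "NRI")
  expect_true(all(tab$family[tab$response %in% gaussians] == "gaussian"))
  expect_true(all(tab$link[tab$response %in% gaussians] == "identity"))
})

test_that("significance codes follow the printed p-value bands", {
  expect_equal(significance_code(c(0.0005, 0.005, 0.03, 0.2, NA)),
               c("***", "**", "*", "ns", NA))
  expect_error(significance_code(1.2))
})

test_that("Poisson GLM recovers a known log-linear cover effect", {
  set.seed(101)
  env <- make_env(500)
  eta <- 1.5 + 0.5 * scale(env$cover)[, 1]
  metrics <- data.frame(plot_id = env$plot_id, S = rpois(500, exp(eta)))
  env$cover <- scale(env$cover)[, 1]
  fit <- fit_metric_glm("S", metrics, env, family = "poisson", link = "log")
  est <- summary(fit)$coefficients["cover", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])
})

test_that("a constant response yields zero chi-square everywhere", {
  env <- make_env(40)
  metrics <- data.frame(plot_id = env$plot_id, GR = rep(2, 40))
  fit <- fit_metric_glm("GR", metrics, env)
  aod <- analysis_of_deviance(fit)
  expect_equal(aod$chi_square, rep(0, 4))
})

test_that("log-link models reject non-positive responses with advice", {
  env <- make_env(30)
  metrics <- data.frame(plot_id = env$plot_id, NRI = rnorm(30))
  expect_error(fit_metric_glm("NRI", metrics, env, family = "poisson",
                              link = "log"), "gaussian")
})

test_that("Gaussian chi-squares equal the scaled RSS reductions (OLS oracle)", {
  set.seed(7)
  env <- make_env(89)
  metrics <- data.frame(plot_id = env$plot_id,
                        GD = rnorm(89, 2 + 0.01 * env$map, 1))
  fit <- fit_metric_glm("GD", metrics, env)
  aod <- analysis_of_deviance(fit)
  df <- merge(metrics, env, by = "plot_id")
  phi <- sum(residuals(lm(GD ~ tmax * map + cover, df))^2) / (89 - 5)
  rss <- function(f) sum(residuals(lm(f, df))^2)
  expect_equal(aod$chi_square[aod$term == "cover"],
               (rss(GD ~ tmax * map) - rss(GD ~ tmax * map + cover)) / phi,
               tolerance = 1e-8)
  expect_equal(aod$chi_square[aod$term == "map"],
               (rss(GD ~ tmax + cover) - rss(GD ~ tmax + map + cover)) / phi,
               tolerance = 1e-8)
  expect_equal(aod$chi_square[aod$term == "tmax:map"],
               (rss(GD ~ tmax + map + cover) - rss(GD ~ tmax * map + cover)) / phi,
               tolerance = 1e-8)
})

test_that("Type-II tests match car::Anova for Poisson and Gaussian fits", {
  set.seed(8)
  env <- make_env(89)
  metrics <- data.frame(plot_id = env$plot_id,
                        S = rpois(89, 15),
                        GR = rnorm(89, 2, 0.5))
  fitp <- fit_metric_glm("S", metrics, env, family = "poisson", link = "log")
  ca <- car::Anova(fitp, type = 2, test.statistic = "LR")
  aod <- analysis_of_deviance(fitp)
  expect_equal(aod$chi_square[match(rownames(ca), aod$term)],
               ca[["LR Chisq"]], tolerance = 1e-8)
  expect_equal(aod$p_value[match(rownames(ca), aod$term)],
               ca[["Pr(>Chisq)"]], tolerance = 1e-8)
})

test_that("quasipoisson chi-square is the Poisson chi-square over the dispersion", {
  set.seed(9)
  env <- make_env(89)
  metrics <- data.frame(plot_id = env$plot_id,
                        CMG = 2 + rpois(89, 6) / 3)
  fq <- fit_metric_glm("CMG", metrics, env, family = "quasipoisson",
                       link = "log")
  fp <- suppressWarnings(
    fit_metric_glm("CMG", metrics, env, family = "poisson", link = "log"))
  aq <- analysis_of_deviance(fq)
  ap <- suppressWarnings(analysis_of_deviance(fp))
  phi <- sum(residuals(fq, type = "pearson")^2) / fq$df.residual
  expect_equal(aq$chi_square, ap$chi_square / phi, tolerance = 1e-8)
  expect_equal(attr(aq, "dispersion"), phi)
})

test_that("a duplicated predictor triggers a singularity error", {
  env <- make_env(30)
  env$map <- env$tmax            # perfectly collinear
  metrics <- data.frame(plot_id = env$plot_id, GR = rnorm(30))
  fit <- suppressWarnings(fit_metric_glm("GR", metrics, env))
  expect_error(analysis_of_deviance(fit), "singular")
})

test_that("NA responses are dropped with their count recorded", {
  env <- make_env(40)
  metrics <- data.frame(plot_id = env$plot_id, PSV = runif(40, 0.4, 1))
  metrics$PSV[c(3, 9)] <- NA
  fit <- fit_metric_glm("PSV", metrics, env)
  expect_equal(attr(fit, "n_dropped"), 2L)
  expect_equal(nrow(fit$model), 38L)
})

test_that("collinearity check reproduces the closed-form t statistic", {
  env <- make_env(20)
  env$map <- env$tmax
  cc <- collinearity_check(env)
  expect_equal(cc$r, 1)

  # exactly orthogonal predictors
  env2 <- make_env(50)
  env2$map <- residuals(lm(map ~ tmax, env2))
  cc2 <- collinearity_check(env2)
  expect_lt(abs(cc2$r), 1e-10)

  # construct tmax/map with exact r = 0.17 at n = 89 via Gram-Schmidt
  set.seed(15)
  n <- 89; r <- 0.17
  x <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ x))
  y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  env3 <- data.frame(tmax = x, map = y)
  cc3 <- collinearity_check(env3)
  expect_equal(cc3$r, 0.17, tolerance = 1e-10)
  expect_equal(cc3$t, 1.61, tolerance = 0.01)
  # agrees with the cor.test oracle
  ct <- cor.test(env3$tmax, env3$map)
  expect_equal(cc3$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(cc3$p_value, ct$p.value, tolerance = 1e-10)

  env4 <- data.frame(tmax = rep(31, 10), map = rnorm(10))
  expect_warning(cc4 <- collinearity_check(env4), "constant")
  expect_true(is.na(cc4$r))
})

test_that("gradient_models stacks a report row per response and term", {
  set.seed(33)
  env <- make_env(60)
  metrics <- data.frame(plot_id = env$plot_id,
                        S = rpois(60, 12) + 1L,
                        invSimpson = runif(60, 1, 8),
                        CMG = runif(60, 2, 5))
  gm <- gradient_models(metrics, env)
  expect_setequal(names(gm$fits), c("S", "invSimpson", "CMG"))
  expect_equal(nrow(gm$report), 3 * 4)
  expect_setequal(unique(gm$report$term),
                  c("tmax", "map", "tmax:map", "cover"))
  expect_true(all(gm$report$stars %in% c("***", "**", "*", "ns")))
  expect_true(all(gm$report$chi_square >= 0))
})
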