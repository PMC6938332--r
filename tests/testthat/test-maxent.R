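fit_values <- releaseflow:::fit_maxent_values

test_that("with no informative covariates the model stays uniform", {
  pc <- matrix(1, 50, 1, dimnames = list(NULL, "f"))
  bc <- matrix(1, 200, 1, dimnames = list(NULL, "f"))
  mod <- fit_values(pc, bc, maxent_settings())
  raw <- predict_maxent(mod, bc, "raw")
  expect_equal(raw, rep(1 / 200, 200))
  expect_equal(mod$gain, 0)
  expect_equal(unname(predict_maxent(mod, bc, "logistic")), rep(0.5, 200))
})

test_that("single-feature Gibbs truth is recovered within tolerance", {
  lams <- vapply(1:3, recover_lambda, numeric(1))
  expect_true(all(abs(lams - 2.0) <= 0.3))
})

test_that("fitted model satisfies the L1 stationarity (KKT box) conditions", {
  set.seed(4)
  bc <- cbind(a = runif(1500), b = runif(1500))
  pres_idx <- sample(1500, 400, replace = TRUE, prob = exp(1.5 * bc[, "a"]))
  pc <- bc[pres_idx, , drop = FALSE]
  mod <- fit_values(pc, bc, maxent_settings())
  # feature expectations under the model vs presence means: the gradient of
  # the smooth part must lie in [-beta, beta] at optimum (|.| = beta on
  # active features)
  Sb <- sweep(sweep(releaseflow:::feature_matrix(bc, mod$features),
                    2, mod$feature_min), 2, mod$feature_range, "/")
  Sp <- sweep(sweep(releaseflow:::feature_matrix(pc, mod$features),
                    2, mod$feature_min), 2, mod$feature_range, "/")
  q <- predict_maxent(mod, bc, "raw")
  grad <- colMeans(Sp) - as.vector(t(Sb) %*% q)
  expect_true(all(abs(grad) <= mod$beta + 1e-4))
  active <- mod$lambda != 0
  expect_true(all(abs(abs(grad[active]) - mod$beta[active]) < 1e-4))
})

test_that("raw probabilities normalise and the gain trace is monotone", {
  set.seed(9)
  bc <- cbind(a = rnorm(800), b = rnorm(800))
  pc <- bc[sample(800, 200, replace = TRUE, prob = exp(bc[, "b"])), ]
  mod <- fit_values(pc, bc, maxent_settings())
  expect_lt(abs(sum(predict_maxent(mod, bc, "raw")) - 1), 1e-8)
  expect_true(all(diff(mod$gain_trace) > -1e-12))
  expect_true(all(mod$gain_trace >= 0))
})

test_that("clamping pins extrapolated predictions at the training boundary", {
  set.seed(2)
  bc <- cbind(a = runif(500, 0, 1))
  pc <- cbind(a = runif(100, 0.5, 1))
  mod <- fit_values(pc, bc, maxent_settings())
  out_of_range <- predict_maxent(mod, cbind(a = c(5, 100)), "logistic")
  at_bound <- predict_maxent(mod, cbind(a = c(1, 1)), "logistic")
  expect_equal(out_of_range, at_bound)
})

test_that("monotone link recovery: prediction non-decreasing in the covariate", {
  set.seed(6)
  bc <- cbind(a = runif(1000))
  pc <- cbind(a = sample(bc[, "a"], 300, replace = TRUE,
                         prob = exp(2.5 * bc[, "a"])))
  mod <- fit_values(pc, bc, maxent_settings(features = "linear"))
  grid <- cbind(a = seq(0, 1, length.out = 50))
  expect_true(all(diff(predict_maxent(mod, grid, "logistic")) >= 0))
  # mean logistic over training background sits near one half
  m_log <- mean(predict_maxent(mod, bc, "logistic"))
  expect_gt(m_log, 0.3); expect_lt(m_log, 0.7)
})

test_that("projection over a stack demands every model covariate", {
  w <- tiny_world(seed = 19)
  tel <- simulate_telemetry(w$truth, w$site, w$cfg, w$land$ocean)
  moves <- thin_daily(exclude_zones(filter_flight_points(tel), w$site, w$land$ocean))
  bg <- build_background(moves, w$site, w$land$ocean,
                         filter_config(n_background = 1000))
  mod <- fit_maxent(moves, bg, w$land)
  surf <- predict_logistic(mod, w$land)
  expect_true(all(surf$values > 0 & surf$values < 1))
  crippled <- w$land
  crippled$covariates <- crippled$covariates[-1]
  expect_error(predict_logistic(mod, crippled), "lacks")
})

test_that("cross-validation partitions presences and scores with rank AUC", {
  w <- tiny_world(seed = 23)
  tel <- simulate_telemetry(w$truth, w$site, w$cfg, w$land$ocean)
  moves <- thin_daily(exclude_zones(filter_flight_points(tel), w$site, w$land$ocean))
  bg <- build_background(moves, w$site, w$land$ocean,
                         filter_config(n_background = 800))
  cv <- crossvalidate(moves, bg, w$land, k = 5, seed = 2)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sort(unique(cv$fold_ids)), 1:5)
  expect_length(cv$fold_ids, nrow(moves))
  expect_true(all(cv$folds$auc >= 0 & cv$folds$auc <= 1))
  expect_equal(cv$mean_auc, mean(cv$folds$auc))
})

test_that("rank AUC equals the brute-force Mann-Whitney count", {
  set.seed(10)
  sp <- rnorm(50, 1); sb <- rnorm(50)
  cnt <- 0
  for (i in 1:50) for (j in 1:50)
    cnt <- cnt + (sp[i] > sb[j]) + 0.5 * (sp[i] == sb[j])
  expect_equal(releaseflow:::auc_mw(sp, sb), cnt / 2500)
})

test_that("separable synthetic data yields near-perfect test AUC", {
  set.seed(5)
  r <- rf_raster(matrix(seq(0, 1, length.out = 900), 30, 30), cell_size = 1000)
  stack <- covariate_stack(list(grad = r))
  cc <- cell_centres(r)
  v <- r$values[cbind(cc$row, cc$col)]
  hi <- which(v > 0.8); lo <- which(v < 0.5)
  pres <- data.frame(x = cc$x[sample(hi, 200, TRUE)],
                     y = cc$y[sample(hi, 200, TRUE)])
  bg <- data.frame(x = cc$x[sample(lo, 800, TRUE)],
                   y = cc$y[sample(lo, 800, TRUE)])
  cv <- crossvalidate(pres, bg, stack, k = 5, seed = 4)
  expect_gt(cv$mean_auc, 0.95)
})

test_that("model selection minimises mean AIC with a sparsity tie-break", {
  ev <- function(aic, ncov) structure(list(mean_aic = aic, n_covariates = ncov),
                                      class = "maxent_cv")
  expect_equal(select_model(list(only = ev(10, 2))), "only")
  expect_equal(select_model(list(a = ev(10, 1), b = ev(5, 2), c = ev(7, 1))), "b")
  expect_equal(select_model(list(a = ev(5, 3), b = ev(5, 1))), "b")
})

test_that("percent contributions normalise to 100 and favour the driver", {
  set.seed(31)
  bc <- cbind(main = runif(1200), noise = runif(1200))
  pc <- bc[sample(1200, 400, replace = TRUE, prob = exp(3 * bc[, "main"])), ]
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    pc_s <- bc[sample(1200, 400, replace = TRUE, prob = exp(3 * bc[, "main"])), ]
    mod <- fit_values(pc_s, bc, maxent_settings())
    pcnt <- percent_contribution(mod)
    expect_equal(sum(pcnt), 100, tolerance = 0.1)
    if (which.max(pcnt) == 1) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # single covariate: all of it
  mod1 <- fit_values(pc[, "main", drop = FALSE], bc[, "main", drop = FALSE],
                     maxent_settings())
  expect_equal(unname(percent_contribution(mod1)), 100)
})
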