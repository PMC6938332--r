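#' Settings for the maximum-entropy conductance model
#'
#' The model class mirrors the classic presence-background MaxEnt setup
#' restricted to linear and quadratic features: a Gibbs distribution over
#' background cells maximising the L1-regularised log-likelihood of the
#' presence sample, with features scaled to [0,1] over the background and
#' clamped to their training range at projection time.
#'
#' @param features feature classes to use: subset of
#'   `c("linear", "quadratic")`.
#' @param beta_multiplier scales the default regularisation; 1 uses the
#'   published sample-size-keyed defaults for linear/quadratic feature sets.
#' @param max_iter cap on single-feature coordinate updates (default 5,000).
#' @param tol stop when a full cycle improves the regularised gain by less.
#' @return list of class `maxent_settings`.
#' @export
maxent_settings <- function(features = c("linear", "quadratic"),
                            beta_multiplier = 1.0, max_iter = 5000,
                            tol = 1e-7) {
  features <- match.arg(features, c("linear", "quadratic"), several.ok = TRUE)
  structure(as.list(environment()), class = "maxent_settings")
}

# published default regularisation multiplier for linear+quadratic feature
# sets, interpolated on presence sample size
default_beta <- function(m) {
  xs <- c(10, 17, 30, 100); ys <- c(0.65, 0.50, 0.25, 0.05)
  if (m <= xs[1]) return(ys[1])
  if (m >= xs[4]) return(ys[4])
  stats::approx(xs, ys, xout = m)$y
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# build the raw (unscaled) feature matrix from covariate values
feature_matrix <- function(covs, features) {
  out <- list()
  for (nm in colnames(covs)) {
    v <- covs[, nm]
    if ("linear" %in% features) out[[paste0(nm, ".linear")]] <- v
    if ("quadratic" %in% features) out[[paste0(nm, ".quadratic")]] <- v^2
  }
  do.call(cbind, out)
}

# covariate values at points from a stack
covariates_at <- function(stack, points, covariate_names = names(stack$covariates)) {
  vals <- sapply(stack$covariates[covariate_names], function(r)
    raster_value_at(r, points$x, points$y))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(covariate_names))
  colnames(vals) <- covariate_names
  vals
}

#' Fit a maximum-entropy presence-background model
#'
#' Maximises the regularised gain
#' `mean_presence(eta) - log mean_background(exp(eta)) - sum(beta * |lambda|)`
#' by cyclic coordinate descent with soft-thresholded proximal Newton updates
#' and backtracking, capped at `max_iter` single-feature updates. Duplicate
#' presence records are retained. Per-update gain increments are recorded per
#' feature for [percent_contribution()].
#'
#' @param presence,background data.frames with `x`, `y`; background is the
#'   cell sample defining the model's state space.
#' @param stack a `covariate_stack` supplying covariate values.
#' @param settings a [maxent_settings()].
#' @param covariate_names covariates to include (default: all in the stack).
#' @return An object of class `maxent_model`: lambdas, feature scaling and
#'   clamp bounds, normaliser, entropy, regularisation, gain trace.
#' @export
fit_maxent <- function(presence, background, stack,
                       settings = maxent_settings(),
                       covariate_names = names(stack$covariates)) {
  stopifnot(nrow(presence) >= 10, nrow(background) >= nrow(presence))
  pc <- covariates_at(stack, presence, covariate_names)
  bc <- covariates_at(stack, background, covariate_names)
  if (any(!is.finite(pc)) || any(!is.finite(bc)))
    stop("non-finite covariate values at presence or background points")
  fit_maxent_values(pc, bc, settings)
}

# core fitter on covariate-value matrices (used directly in tests)
fit_maxent_values <- function(pc, bc, settings = maxent_settings()) {
  Fp <- feature_matrix(pc, settings$features)
  Fb <- feature_matrix(bc, settings$features)
  # scale each feature to [0,1] over background; constants stored for
  # projection ("projected to the entire study area" from these constants)
  fmin <- apply(Fb, 2, min); fmax <- apply(Fb, 2, max)
  rng <- pmax(fmax - fmin, .Machine$double.eps)
  scale_f <- function(M) sweep(sweep(M, 2, fmin), 2, rng, "/")
  Sp <- scale_f(Fp); Sb <- scale_f(Fb)

  m <- nrow(Sp); n <- nrow(Sb); nf <- ncol(Sp)
  beta <- settings$beta_multiplier * default_beta(m) *
    pmax(apply(Sp, 2, sd), 1e-6) / sqrt(m)

  lambda <- setNames(numeric(nf), colnames(Sp))
  eta_b <- rep(0, n)
  mp <- colMeans(Sp)   # presence feature means (the moment constraints)

  gain_fun <- function(lam, eb) {
    sum(lam * mp) - (logsumexp(eb) - log(n)) - sum(beta * abs(lam))
  }
  gain <- gain_fun(lambda, eta_b)   # = 0 at the uniform start
  trace_feat <- character(0); trace_inc <- numeric(0); trace_gain <- gain

  iter <- 0L
  repeat {
    cycle_start <- gain
    for (j in seq_len(nf)) {
      if (iter >= settings$max_iter) break
      iter <- iter + 1L
      w <- exp(eta_b - logsumexp(eta_b))
      eq <- sum(w * Sb[, j])
      vq <- sum(w * (Sb[, j] - eq)^2)
      if (vq < 1e-8) next
      u <- lambda[j] + (mp[j] - eq) / vq
      lam_new <- sign(u) * max(0, abs(u) - beta[j] / vq)
      delta <- lam_new - lambda[j]
      # features live in [0,1], so |lambda| ~ 50 is already saturation;
      # capping the step keeps near-degenerate directions finite
      delta <- sign(delta) * min(abs(delta), 50)
      if (delta == 0) next
      # backtracking on the true regularised gain
      step <- 1
      repeat {
        cand <- lambda; cand[j] <- lambda[j] + step * delta
        eb_new <- eta_b + step * delta * Sb[, j]
        g_new <- gain_fun(cand, eb_new)
        if ((is.finite(g_new) && g_new >= gain - 1e-12) || step < 1e-6) break
        step <- step / 2
      }
      if (!is.finite(g_new)) next
      if (g_new > gain) {
        trace_feat <- c(trace_feat, colnames(Sp)[j])
        trace_inc <- c(trace_inc, g_new - gain)
        lambda <- cand; eta_b <- eb_new; gain <- g_new
        trace_gain <- c(trace_gain, gain)
      }
    }
    if (iter >= settings$max_iter || gain - cycle_start < settings$tol) break
  }

  logZ <- logsumexp(eta_b)                  # raw normaliser: sum(raw) = 1
  q <- exp(eta_b - logZ)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(
    lambda = lambda, beta = beta,
    feature_min = fmin, feature_range = rng,
    covariates = colnames(pc), features = settings$features,
    logZ = logZ, log_n_background = log(n), entropy = entropy,
    gain = gain, n_presence = m, n_background = n,
    n_updates = iter,
    trace = data.frame(feature = trace_feat, gain_increment = trace_inc),
    gain_trace = trace_gain,
    converged = iter < settings$max_iter), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features over %d covariates, %d presences\n",
              length(x$lambda), length(x$covariates), x$n_presence))
  cat(sprintf("  regularised gain %.4f, entropy %.4f, %d updates%s\n",
              x$gain, x$entropy, x$n_updates,
              if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

# linear predictor for a covariate-value matrix, with optional clamping of
# scaled features to the training range [0,1]
maxent_eta <- function(model, covs, clamp = TRUE) {
  M <- feature_matrix(covs, model$features)
  S <- sweep(sweep(M, 2, model$feature_min), 2, model$feature_range, "/")
  if (clamp) S <- pmin(pmax(S, 0), 1)
  as.vector(S %*% model$lambda)
}

#' Predict from a fitted maximum-entropy model
#'
#' `type = "raw"` gives the Gibbs probability normalised so the background
#' sample sums to one; `"logistic"` applies the entropy-calibrated transform
#' `c*raw/(1 + c*raw)` with `c = exp(entropy)`, giving values in (0,1) with
#' ~0.5 at cells of typical suitability. With `clamp = TRUE` (default),
#' features outside their training range are fixed at the range boundary, so
#' extrapolated predictions equal boundary predictions.
#'
#' @param model a `maxent_model`.
#' @param covs matrix/data.frame of covariate values (columns named as the
#'   model's covariates).
#' @param type `"logistic"`, `"raw"`, or `"eta"` (linear predictor).
#' @param clamp clamp features to training bounds?
#' @return Numeric vector of predictions.
#' @export
predict_maxent <- function(model, covs, type = c("logistic", "raw", "eta"),
                           clamp = TRUE) {
  type <- match.arg(type)
  covs <- as.matrix(covs)
  missing <- setdiff(model$covariates, colnames(covs))
  if (length(missing))
    stop("missing covariate(s): ", paste(missing, collapse = ", "))
  covs <- covs[, model$covariates, drop = FALSE]
  eta <- maxent_eta(model, covs, clamp)
  if (type == "eta") return(eta)
  raw <- exp(eta - model$logZ)
  if (type == "raw") return(raw)
  cr <- exp(model$entropy) * raw
  cr / (1 + cr)
}

#' Project the logistic conductance surface over a stack
#'
#' @param model a `maxent_model`.
#' @param stack a `covariate_stack` containing every model covariate.
#' @param clamp clamp features to training bounds (default `TRUE`).
#' @return An `rf_raster` of logistic conductance in (0,1).
#' @export
predict_logistic <- function(model, stack, clamp = TRUE) {
  missing <- setdiff(model$covariates, names(stack$covariates))
  if (length(missing))
    stop("stack lacks model covariate(s): ", paste(missing, collapse = ", "))
  ref <- stack$covariates[[1]]
  covs <- sapply(model$covariates, function(nm)
    as.vector(stack$covariates[[nm]]$values))
  out <- ref
  out$values <- matrix(predict_maxent(model, covs, "logistic", clamp),
                       nrow(ref$values), ncol(ref$values))
  out
}

# rank-based (Mann-Whitney) AUC of presence scores vs background scores
auc_mw <- function(score_pres, score_bg) {
  r <- rank(c(score_pres, score_bg))
  m <- length(score_pres); n <- length(score_bg)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# AIC under the ENMTools convention: K = nonzero lambdas, lnL = sum of log
# raw probabilities (renormalised over the background cell sample) of all
# presences; NA when K >= number of presences
maxent_aic <- function(model, presence_covs) {
  K <- sum(model$lambda != 0)
  if (K == 0 || K >= model$n_presence) return(NA_real_)
  raw <- predict_maxent(model, presence_covs, "raw")
  if (any(raw <= 0)) return(NA_real_)
  2 * K - 2 * sum(log(raw))
}

#' k-fold cross-validation of a maximum-entropy model
#'
#' Randomly partitions the presences into `k` folds; for each fold, fits on
#' the remaining presences (full background) and records the regularised
#' training gain, rank-based test AUC of withheld presences against the
#' background, and AIC over all presences under the fold model. Means across
#' folds are reported alongside per-fold values.
#'
#' @inheritParams fit_maxent
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold partition.
#' @return list of class `maxent_cv`: `folds` (data.frame), `mean_gain`,
#'   `mean_auc`, `mean_aic`, `n_covariates`, `covariates`, and `fold_ids`.
#' @export
crossvalidate <- function(presence, background, stack, k = 5,
                          settings = maxent_settings(), seed = 1,
                          covariate_names = names(stack$covariates)) {
  stopifnot(nrow(presence) >= k)
  pc <- covariates_at(stack, presence, covariate_names)
  bc <- covariates_at(stack, background, covariate_names)
  fold <- with_seed(seed,
                    sample(rep(seq_len(k), length.out = nrow(presence))))
  res <- vector("list", k)
  for (f in seq_len(k)) {
    train <- pc[fold != f, , drop = FALSE]
    test <- pc[fold == f, , drop = FALSE]
    if (nrow(test) < 1) stop("fold ", f, " has no withheld presences")
    mod <- fit_maxent_values(train, bc, settings)
    auc <- auc_mw(predict_maxent(mod, test, "eta"),
                  predict_maxent(mod, bc, "eta"))
    res[[f]] <- data.frame(fold = f, gain = mod$gain, auc = auc,
                           aic = maxent_aic(mod, pc))
  }
  folds <- do.call(rbind, res)
  structure(list(folds = folds,
                 mean_gain = mean(folds$gain), mean_auc = mean(folds$auc),
                 mean_aic = mean(folds$aic),
                 n_covariates = length(covariate_names),
                 covariates = covariate_names, fold_ids = fold),
            class = "maxent_cv")
}

#' Select the candidate with the lowest mean AIC
#'
#' @param evaluations named list of `maxent_cv` results (one per candidate
#'   covariate set).
#' @return The name (or index, if unnamed) of the winning candidate; ties
#'   broken by fewer covariates.
#' @export
select_model <- function(evaluations) {
  stopifnot(length(evaluations) >= 1)
  aic <- vapply(evaluations, function(e) e$mean_aic, numeric(1))
  ncov <- vapply(evaluations, function(e) e$n_covariates, numeric(1))
  ord <- order(aic, ncov)
  best <- ord[1]
  if (!is.null(names(evaluations))) names(evaluations)[best] else best
}

#' Serialise a fitted model to JSON
#'
#' Stores lambdas, feature scaling/clamp bounds, the normaliser and entropy —
#' everything [predict_maxent()] needs to project to new data.
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `read_maxent_json` returns the restored `maxent_model`.
#' @export
write_maxent_json <- function(model, path) {
  keep <- c("lambda", "beta", "feature_min", "feature_range", "covariates",
            "features", "logZ", "log_n_background", "entropy", "gain",
            "n_presence", "n_background", "n_updates", "converged")
  obj <- lapply(model[keep], function(x)
    if (is.null(names(x))) x else as.list(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("lambda", "beta", "feature_min", "feature_range"))
    obj[[nm]] <- unlist(obj[[nm]])
  obj$trace <- data.frame(feature = character(0), gain_increment = numeric(0))
  structure(obj, class = "maxent_model")
}

#' Percent contribution of each covariate
#'
#' Attributes each coordinate-descent gain increment to the covariate whose
#' feature was updated, sums per covariate, and normalises to 100%.
#'
#' @param model a fitted `maxent_model`.
#' @return Named numeric vector summing to 100 (all zeros if no gain).
#' @export
percent_contribution <- function(model) {
  covs <- model$covariates
  out <- setNames(numeric(length(covs)), covs)
  if (nrow(model$trace) == 0 || sum(model$trace$gain_increment) <= 0)
    return(out)
  cov_of <- sub("\\.(linear|quadratic)$", "", model$trace$feature)
  agg <- tapply(model$trace$gain_increment, cov_of, sum)
  out[names(agg)] <- agg
  100 * out / sum(out)
}
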