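# Classifiers predicting co-occupancy from chromatin features. Two
# non-linear kinds (RBF-kernel SVM, random forest) delegate to established
# implementations; the two linear kinds (Gaussian naive Bayes, linear
# discriminant) are implemented from their closed forms so the
# linear-vs-non-linear contrast is reproducible without opaque
# dependencies. All kinds see z-scored features (statistics taken from the
# training rows only), which the RBF kernel requires and the others
# tolerate.

CLASSIFIER_KINDS <- c("rbf_margin", "tree_ensemble", "gaussian_nb",
                      "linear_discriminant")

#' Specify a classifier
#'
#' @param kind one of `"rbf_margin"` (RBF-kernel SVM), `"tree_ensemble"`
#'   (random forest), `"gaussian_nb"` (Gaussian naive Bayes),
#'   `"linear_discriminant"` (LDA).
#' @param hyper named list of hyperparameters. `rbf_margin`: `cost`
#'   (default 1) and `gamma` (default 1/n_features on standardized data);
#'   `tree_ensemble`: `ntree` (default 500); `linear_discriminant`:
#'   `ridge` (fallback regularisation, default 1e-8).
#' @param seed integer seed used for any stochastic fitting.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = CLASSIFIER_KINDS, hyper = list(),
                            seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyper = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

# sd with a floor so constant features are retained rather than dropped
sd_floored <- function(x, floor = 1e-8) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < floor) floor else s
}

#' Fit a classifier on a feature matrix
#'
#' Rows with missing feature values are dropped with a warning.
#' Standardization statistics (per-feature mean and sd, sd floored for
#' constant features) come from the training rows only and travel with the
#' model so transferred predictions use the training cell's scale.
#'
#' @param spec a [classifier_spec()].
#' @param train a `feature_matrix` with both classes present.
#' @param train_cell,tf_pair optional provenance labels stored on the model.
#' @return object of class `trained_model`.
#' @export
fit_classifier <- function(spec, train, train_cell = NA_character_,
                           tf_pair = NA_character_) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- feature_values(train)
  y <- train$label
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " row(s) with missing features")
    x <- x[keep, , drop = FALSE]; y <- y[keep]
  }
  if (!all(c(0L, 1L) %in% y)) stop("training data must contain both classes")

  center <- colMeans(x)
  scale <- apply(x, 2, sd_floored)
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  fitted <- switch(
    spec$kind,
    rbf_margin = {
      cost <- spec$hyper$cost %||% 1
      gamma <- spec$hyper$gamma %||% (1 / ncol(xs))
      set.seed(spec$seed)
      e1071::svm(x = xs, y = factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = cost, gamma = gamma, scale = FALSE)
    },
    tree_ensemble = {
      ntree <- spec$hyper$ntree %||% 500
      set.seed(spec$seed)
      randomForest::randomForest(x = xs, y = factor(y, levels = c(0, 1)),
                                 ntree = ntree)
    },
    gaussian_nb = fit_gaussian_nb(xs, y),
    linear_discriminant = fit_lda(xs, y, ridge = spec$hyper$ridge %||% 1e-8)
  )

  structure(
    list(spec = spec, feature_names = colnames(x), center = center,
         scale = scale, fitted = fitted, train_cell = train_cell,
         tf_pair = tf_pair),
    class = "trained_model"
  )
}

# Gaussian naive Bayes from its closed form: per-class priors plus
# per-class per-feature means and variances (variance floored).
fit_gaussian_nb <- function(x, y, var_floor = 1e-8) {
  params <- lapply(c(neg = 0L, pos = 1L), function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xc),
         var = pmax(apply(xc, 2, stats::var), var_floor),
         log_prior = log(nrow(xc) / nrow(x)))
  })
  structure(params, class = "gaussian_nb_fit")
}

# NB log-odds of class 1 vs class 0 for standardized rows
score_gaussian_nb <- function(fit, x) {
  ll <- function(p) {
    rowSums(-0.5 * log(2 * pi * rep(1, nrow(x)) %o% p$var) -
              sweep(x, 2, p$mean)^2 / (2 * rep(1, nrow(x)) %o% p$var)) +
      p$log_prior
  }
  ll(fit$pos) - ll(fit$neg)
}

# Fisher linear discriminant from its closed form: pooled within-class
# covariance S, weights w = S^-1 (mu1 - mu0), scores centered at the
# midpoint with a log-prior offset. Singular S falls back to a ridge.
fit_lda <- function(x, y, ridge = 1e-8) {
  x1 <- x[y == 1L, , drop = FALSE]; x0 <- x[y == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  s <- ((n1 - 1) * stats::cov(x1) + (n0 - 1) * stats::cov(x0)) / (n1 + n0 - 2)
  w <- tryCatch(solve(s, mu1 - mu0), error = function(e) {
    solve(s + diag(ridge * mean(diag(s)) + ridge, ncol(x)), mu1 - mu0)
  })
  structure(list(w = w, mu1 = mu1, mu0 = mu0,
                 log_prior_ratio = log(n1 / n0)),
            class = "lda_fit")
}

score_lda <- function(fit, x) {
  drop(x %*% fit$w) - sum(fit$w * (fit$mu1 + fit$mu0)) / 2 +
    fit$log_prior_ratio
}

#' Score rows with a trained model
#'
#' Returns one real score per row, oriented so that higher means more
#' co-occupied-like, centered so 0 is the natural decision threshold for
#' every kind: log-odds for the closed-form kinds, the signed SVM decision
#' value, and the forest's class-1 vote fraction minus 1/2.
#'
#' @param model a `trained_model`.
#' @param fm a `feature_matrix` containing the model's features.
#' @return numeric scores.
#' @export
score_classifier <- function(model, fm) {
  stopifnot(inherits(model, "trained_model"))
  fn_have <- attr(fm, "feature_names")
  miss <- setdiff(model$feature_names, fn_have)
  extra <- setdiff(fn_have, model$feature_names)
  if (length(miss)) {
    stop("feature mismatch; missing from data: ",
         paste(miss, collapse = ", "),
         if (length(extra)) paste0("; extra in data: ",
                                   paste(extra, collapse = ", ")) else "")
  }
  x <- feature_values(fm, model$feature_names)
  if (anyNA(x)) stop("missing feature values; drop or impute before scoring")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")

  switch(
    model$spec$kind,
    rbf_margin = {
      dv <- attr(stats::predict(model$fitted, xs, decision.values = TRUE),
                 "decision.values")
      lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
      if (lab[1] == "1") drop(dv) else -drop(dv)
    },
    tree_ensemble = {
      unname(stats::predict(model$fitted, xs, type = "prob")[, "1"] - 0.5)
    },
    gaussian_nb = score_gaussian_nb(model$fitted, xs),
    linear_discriminant = score_lda(model$fitted, xs)
  )
}

#' Serialize a closed-form model to versioned JSON
#'
#' Supported for the closed-form kinds (`gaussian_nb`,
#' `linear_discriminant`), whose parameters are plain numbers and therefore
#' portable across cells by construction; the margin and ensemble kinds are
#' opaque third-party fits and are kept as R objects instead.
#'
#' @param model a `trained_model` of a closed-form kind.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (!model$spec$kind %in% c("gaussian_nb", "linear_discriminant")) {
    stop("JSON serialization is supported for gaussian_nb and ",
         "linear_discriminant only")
  }
  obj <- list(
    format_version = 1L,
    kind = model$spec$kind,
    seed = model$spec$seed,
    feature_names = model$feature_names,
    center = as.list(model$center),
    scale = as.list(model$scale),
    train_cell = model$train_cell,
    tf_pair = model$tf_pair,
    parameters = rapply(unclass(model$fitted), identity, how = "list")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#' @param path JSON file.
#' @return a `trained_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) unlist(v)
  fitted <- if (obj$kind == "gaussian_nb") {
    structure(lapply(obj$parameters, function(p)
      list(mean = num(p$mean), var = num(p$var),
           log_prior = p$log_prior)), class = "gaussian_nb_fit")
  } else {
    structure(list(w = num(obj$parameters$w), mu1 = num(obj$parameters$mu1),
                   mu0 = num(obj$parameters$mu0),
                   log_prior_ratio = obj$parameters$log_prior_ratio),
              class = "lda_fit")
  }
  structure(
    list(spec = classifier_spec(obj$kind, seed = obj$seed),
         feature_names = obj$feature_names,
         center = num(obj$center), scale = num(obj$scale),
         fitted = fitted,
         train_cell = obj$train_cell, tf_pair = obj$tf_pair),
    class = "trained_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
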