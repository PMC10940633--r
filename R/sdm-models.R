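#' Fit a binomial GAM species distribution model
#'
#' One thin-plate smooth per predictor with basis dimension capped at
#' `k_max` (default 4, i.e. at most 3 effective degrees of freedom per
#' term), binomial family with logit link, no interactions. The low basis
#' cap keeps the response curves ecologically smooth and guards against
#' overfitting the sparse deep-water data.
#'
#' @param train data.frame with a 0/1 `detected` column and the predictor
#'   columns.
#' @param predictors character vector of predictor column names; defaults
#'   to the dataset's `"predictors"` attribute.
#' @param k_max basis dimension per smooth.
#' @return object of class `sdm_model`.
#' @export
fit_gam <- function(train, predictors = attr(train, "predictors"),
                    k_max = 4) {
  check_training(train, predictors)
  form <- stats::as.formula(paste(
    "detected ~",
    paste(sprintf("s(%s, k = %d)", predictors, k_max), collapse = " + ")))
  fit <- tryCatch(
    mgcv::gam(form, family = stats::binomial(link = "logit"), data = train),
    error = function(e) stop("GAM fit failed: ", conditionMessage(e)))
  if (!fit$converged) stop("GAM did not converge")
  structure(list(algorithm = "gam", fit = fit,
                 predictor_names = predictors),
            class = "sdm_model")
}

#' Fit a random-forest species distribution model
#'
#' A probability forest (per-tree class-vote fractions averaged over
#' trees) on classification trees, deterministic for a given seed.
#'
#' @param train as in [fit_gam()].
#' @param predictors predictor column names.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed controlling bootstrap and split randomness.
#' @return object of class `sdm_model`.
#' @export
fit_rf <- function(train, predictors = attr(train, "predictors"),
                   n_trees = 500, seed = 1L) {
  check_training(train, predictors)
  fit <- ranger::ranger(
    x = train[predictors],
    y = factor(train$detected, levels = c(0, 1)),
    num.trees = n_trees, probability = TRUE,
    seed = seed, num.threads = 1)
  structure(list(algorithm = "rf", fit = fit,
                 predictor_names = predictors),
            class = "sdm_model")
}

check_training <- function(train, predictors) {
  if (is.null(predictors) || length(predictors) == 0)
    stop("no predictors given")
  missing_cols <- setdiff(c("detected", predictors), names(train))
  if (length(missing_cols))
    stop("training data lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyNA(train[c("detected", predictors)]))
    stop("missing values in training data")
  if (sum(train$detected == 1) < 2 || sum(train$detected == 0) < 2)
    stop("training data needs at least 2 presences and 2 absences")
  invisible(TRUE)
}

#' Predict occurrence probability from a fitted model
#'
#' @param object an `sdm_model`.
#' @param newdata data.frame containing all predictor columns.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.sdm_model <- function(object, newdata, ...) {
  miss <- setdiff(object$predictor_names, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "))
  if (object$algorithm == "gam") {
    as.numeric(stats::predict(object$fit, newdata, type = "response"))
  } else {
    stats::predict(object$fit, data = newdata[object$predictor_names],
                   num.threads = 1)$predictions[, "1"]
  }
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s on %s\n", toupper(x$algorithm),
              paste(x$predictor_names, collapse = ", ")))
  invisible(x)
}

#' Predict a probability map over a stack
#'
#' Evaluates the model at every grid cell of the stack; cells where any
#' predictor is nodata are nodata.
#'
#' @param model an `sdm_model`.
#' @param stack a [predictor_stack()] providing every predictor layer.
#' @return [raster_layer()] of probabilities.
#' @export
predict_map <- function(model, stack) {
  miss <- setdiff(model$predictor_names, names(stack$layers))
  if (length(miss))
    stop("stack lacks layer(s): ", paste(miss, collapse = ", "))
  tab <- stack_table(stack)
  ok <- stats::complete.cases(tab[model$predictor_names])
  out <- rep(NA_real_, nrow(tab))
  if (any(ok)) out[ok] <- predict(model, tab[ok, , drop = FALSE])
  g <- stack$grid
  raster_layer(g, matrix(out, g$n_rows, g$n_cols, byrow = TRUE),
               name = paste0("suitability_", model$algorithm),
               units = "probability")
}

#' Partial-dependence response curve
#'
#' The response to one predictor, marginalising the others over an
#' observed background: for each grid value x of the predictor, the curve
#' is the mean prediction over the background rows with that predictor
#' overwritten by x. Well-defined for both learners and directly
#' averageable across models.
#'
#' @param model an `sdm_model`.
#' @param predictor one of the model's predictors.
#' @param background data.frame of observed predictor combinations
#'   (typically the training table).
#' @param n_points number of x values spanning the background range.
#' @return object of class `response_curve`: data.frame with columns `x`,
#'   `y` and attribute `"predictor"`.
#' @export
response_curve <- function(model, predictor, background, n_points = 100) {
  if (!predictor %in% model$predictor_names)
    stop("'", predictor, "' is not a model predictor")
  rng <- range(background[[predictor]])
  if (diff(rng) == 0)
    stop("predictor '", predictor, "' is constant in the background")
  xs <- seq(rng[1], rng[2], length.out = n_points)
  bg <- background[rep(seq_len(nrow(background)), times = n_points),
                   model$predictor_names, drop = FALSE]
  bg[[predictor]] <- rep(xs, each = nrow(background))
  p <- predict(model, bg)
  y <- rowsum(p, group = rep(seq_len(n_points), each = nrow(background)))
  y <- as.numeric(y) / nrow(background)
  structure(data.frame(x = xs, y = y),
            predictor = predictor, class = c("response_curve", "data.frame"))
}

#' Average response curves over models on a common grid
#'
#' Interpolates each curve onto an x grid spanning the intersection of
#' all curves' ranges and averages the interpolated values.
#'
#' @param curves list of [response_curve()]s for one predictor.
#' @param n_points size of the common grid.
#' @return a `response_curve` (the mean curve).
#' @export
mean_response_curve <- function(curves, n_points = 200) {
  stopifnot(length(curves) >= 1)
  lo <- max(vapply(curves, function(cv) min(cv$x), 0))
  hi <- min(vapply(curves, function(cv) max(cv$x), 0))
  if (hi <= lo) stop("response curves have no common x range")
  xs <- seq(lo, hi, length.out = n_points)
  ys <- vapply(curves,
               function(cv) stats::approx(cv$x, cv$y, xout = xs)$y,
               numeric(n_points))
  structure(data.frame(x = xs, y = rowMeans(ys)),
            predictor = attr(curves[[1]], "predictor"),
            class = c("response_curve", "data.frame"))
}
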