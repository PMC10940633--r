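#' Area under the ROC curve
#'
#' The probability that a randomly chosen presence receives a higher
#' prediction than a randomly chosen absence, with ties counted one half
#' (the Mann-Whitney form, computed from average ranks).
#'
#' @param obs 0/1 observations.
#' @param pred numeric predictions of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(obs, pred) {
  check_two_class(obs, pred)
  r <- rank(pred)
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_two_class <- function(obs, pred = NULL) {
  if (!all(obs %in% c(0, 1))) stop("obs must be 0/1")
  if (!is.null(pred) && length(pred) != length(obs))
    stop("obs and pred lengths differ")
  if (sum(obs == 1) == 0 || sum(obs == 0) == 0)
    stop("both classes must be present")
  invisible(TRUE)
}

#' Confusion-matrix metrics at a threshold
#'
#' A record is classified presence iff `pred >= threshold` (the closed
#' side is on presence throughout the package). TSS = sensitivity +
#' specificity - 1.
#'
#' @param obs 0/1 observations.
#' @param pred predictions.
#' @param threshold classification threshold.
#' @return named list: `sensitivity`, `specificity`, `tss`.
#' @export
confusion_metrics <- function(obs, pred, threshold) {
  check_two_class(obs, pred)
  pos <- pred >= threshold
  sens <- sum(pos & obs == 1) / sum(obs == 1)
  spec <- sum(!pos & obs == 0) / sum(obs == 0)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Threshold maximising the True Skill Statistic
#'
#' Scans the candidate set (the sorted unique predictions plus 0 and 1)
#' and returns the smallest candidate attaining the maximal TSS. Taking
#' the smallest maximiser favours sensitivity, appropriate when missing a
#' presence is costlier than a false alarm.
#'
#' @param obs 0/1 observations.
#' @param pred predictions.
#' @return the optimal threshold.
#' @export
optimal_tss_threshold <- function(obs, pred) {
  check_two_class(obs, pred)
  cand <- sort(unique(c(0, 1, pred)))
  p1 <- pred[obs == 1]; p0 <- pred[obs == 0]
  tss <- vapply(cand,
                function(t) mean(p1 >= t) + mean(p0 < t) - 1,
                numeric(1))
  # smallest maximiser, with a fp tolerance so exact ties are not broken
  # by rounding noise
  cand[which(tss >= max(tss) - 1e-12)[1]]
}

#' Permutation importance as AUC loss
#'
#' For each predictor, the evaluation table's column is shuffled (the
#' others fixed), the model re-predicted, and the drop in AUC recorded;
#' the mean over `n_permutations` shuffles is reported. Negative losses
#' (a permutation that happens to help) are reported as-is.
#'
#' @param model an `sdm_model`.
#' @param eval_table data.frame with `detected` and the predictor columns,
#'   both classes present.
#' @param n_permutations shuffles per predictor (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `predictor`, `auc_loss`,
#'   `n_permutations`.
#' @export
permutation_importance <- function(model, eval_table, n_permutations = 10,
                                   seed = 1L) {
  stopifnot(n_permutations >= 1)
  obs <- eval_table$detected
  check_two_class(obs)
  base <- roc_auc(obs, predict(model, eval_table))
  with_seed(derive_seed(seed, 6L), {
    loss <- vapply(model$predictor_names, function(pn) {
      aucs <- vapply(seq_len(n_permutations), function(i) {
        tab <- eval_table
        tab[[pn]] <- sample(tab[[pn]])
        roc_auc(obs, predict(model, tab))
      }, numeric(1))
      base - mean(aucs)
    }, numeric(1))
    data.frame(predictor = model$predictor_names,
               auc_loss = unname(loss),
               n_permutations = n_permutations,
               row.names = NULL)
  })
}

#' Pairwise rank-correlation collinearity report
#'
#' Advisory Spearman correlation screening of the predictors; nothing is
#' dropped automatically.
#'
#' @param dataset model-ready dataset with predictor columns (attribute
#'   `"predictors"` or explicit `predictors`).
#' @param predictors predictor names.
#' @param threshold absolute correlation above which a pair is flagged.
#' @return data.frame of predictor pairs with `rho` and `flagged`.
#' @export
collinearity_report <- function(dataset,
                                predictors = attr(dataset, "predictors"),
                                threshold = 0.7) {
  if (nrow(dataset) < 3) stop("need at least 3 records")
  m <- as.matrix(dataset[predictors])
  constant <- apply(m, 2, function(x) stats::sd(x) == 0)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  out <- data.frame(
    var1 = predictors[pairs[, 1]], var2 = predictors[pairs[, 2]],
    rho = rho[pairs], row.names = NULL)
  undef <- constant[pairs[, 1]] | constant[pairs[, 2]]
  out$rho[undef] <- NA_real_
  out$flagged <- !is.na(out$rho) & abs(out$rho) > threshold
  out
}
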