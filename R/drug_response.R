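## Per-compound elastic-net models of drug sensitivity (AUC) on factor
## loadings or raw molecular features, with seeded cross-validation so the
## factor-based and raw-feature-based runs share identical fold partitions.

#' Seeded cross-validation fold memberships
#'
#' A deterministic function of (n, folds, seed) only, so models trained on
#' different predictor matrices over the same samples share byte-identical
#' partitions.
#'
#' @param n number of samples.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..folds.
#' @export
cv_folds <- function(n, folds = 10, seed = 1L) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(folds), n))
}

#' Fit an elastic-net drug-response model
#'
#' Linear elastic net of one compound's response on the predictor matrix
#' (factor loadings or raw features). The regularization penalty lambda is
#' chosen by seeded k-fold cross-validation at minimum loss; predictors are
#' standardized internally by the solver (glmnet default), appropriate since
#' factor scales differ.
#'
#' @param predictors samples x p numeric matrix.
#' @param response named or aligned per-sample response (AUC; lower = more
#'   sensitive). Missing entries drop the sample for this compound.
#' @param alpha elastic-net mixing parameter in [0, 1] (default 0.5).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold partition.
#' @param compound label stored in the result.
#' @return An object of class \code{"drug_model"}: coefficients (named, at
#'   lambda.min), intercept, lambda, alpha, \code{cv_performance} (Pearson r
#'   between out-of-fold CV predictions and observed response),
#'   \code{n_selected}, fold ids and sample ids used.
#' @export
fit_drug_model <- function(predictors, response, alpha = 0.5, folds = 10,
                           seed = 1L, compound = "compound") {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(response)
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 3 * folds)
    stop("fit_drug_model: need at least 3 x folds samples with observed response")
  sample_ids <- rownames(X) %||% as.character(which(keep))
  if (stats::sd(y) == 0) {
    ans <- list(compound = compound, coefficients = stats::setNames(rep(0, ncol(X)), colnames(X)),
                intercept = y[1], lambda = NA_real_, alpha = alpha,
                cv_performance = NA_real_, n_selected = 0L,
                fold_id = NULL, sample_ids = sample_ids, constant_response = TRUE)
    class(ans) <- "drug_model"
    return(ans)
  }
  foldid <- cv_folds(n, folds, seed)
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid, keep = TRUE,
                          standardize = TRUE)
  i <- which(cv$lambda == cv$lambda.min)[1]
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- c("(Intercept)", colnames(X))
  oof <- cv$fit.preval[, i]
  ans <- list(compound = compound,
              coefficients = beta[-1], intercept = beta[1],
              lambda = cv$lambda.min, alpha = alpha,
              cv_performance = suppressWarnings(stats::cor(oof, y)),
              n_selected = sum(beta[-1] != 0),
              fold_id = foldid, sample_ids = sample_ids,
              constant_response = FALSE)
  class(ans) <- "drug_model"
  ans
}

#' @export
print.drug_model <- function(x, ...) {
  cat(sprintf("drug_model '%s': %d/%d predictors selected (alpha = %.2f)\n",
              x$compound, x$n_selected, length(x$coefficients), x$alpha))
  if (isTRUE(x$constant_response)) cat("  constant response: intercept-only model\n")
  else cat(sprintf("  lambda.min = %.4g, CV r = %.3f\n", x$lambda, x$cv_performance))
  invisible(x)
}

#' Predict response for new samples from a drug model
#'
#' @param object a \code{drug_model}.
#' @param newdata samples x p matrix over the same predictors (matched by
#'   column name when both are named).
#' @param ... unused.
#' @return per-sample predicted response.
#' @export
predict.drug_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  b <- object$coefficients
  if (!is.null(colnames(X)) && !is.null(names(b)) && all(names(b) %in% colnames(X)))
    X <- X[, names(b), drop = FALSE]
  if (ncol(X) != length(b)) stop("predict.drug_model: predictor mismatch")
  drop(object$intercept + X %*% b)
}

#' Nested double-loop cross-validated prediction performance
#'
#' Outer folds are held out entirely; within each outer training set an inner
#' seeded CV selects lambda; performance is the Pearson r between the
#' concatenated out-of-fold predictions and the observations. The outer
#' partition is a deterministic function of (n, outer_folds, seed), so runs on
#' factor loadings and on raw features over the same samples share identical
#' partitions.
#'
#' @inheritParams fit_drug_model
#' @param outer_folds,inner_folds fold counts (default 10 each).
#' @return list with \code{r}, \code{predictions} (data frame: sample, fold,
#'   observed, predicted), \code{fold_id}, and any skipped folds.
#' @export
nested_cv_performance <- function(predictors, response, outer_folds = 10,
                                  inner_folds = 10, alpha = 0.5, seed = 1L) {
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  if (n < 3 * outer_folds)
    stop("nested_cv_performance: need at least 3 x outer_folds observed samples")
  fold_id <- cv_folds(n, outer_folds, seed)
  pred <- rep(NA_real_, n)
  skipped <- integer(0)
  for (f in seq_len(outer_folds)) {
    tr <- fold_id != f; te <- !tr
    if (stats::sd(y[tr]) == 0) {
      warning("nested_cv_performance: zero response variance in training fold ", f,
              "; fold skipped")
      skipped <- c(skipped, f)
      next
    }
    inner_id <- cv_folds(sum(tr), inner_folds, seed = as.integer(seed) + f)
    cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                            foldid = inner_id, standardize = TRUE)
    pred[te] <- as.numeric(stats::predict(cv, X[te, , drop = FALSE], s = "lambda.min"))
  }
  ok <- !is.na(pred)
  r <- suppressWarnings(stats::cor(pred[ok], y[ok]))
  list(r = r,
       predictions = data.frame(sample = (rownames(X) %||% as.character(seq_len(n)))[ok],
                                fold = fold_id[ok], observed = y[ok],
                                predicted = pred[ok]),
       fold_id = fold_id, skipped_folds = skipped)
}

#' Relative contribution of each predictor to a drug model
#'
#' contribution_j = mean over samples of |beta_j x_ij|, normalized to sum to 1
#' over the predictors with nonzero coefficient.
#'
#' @param model a fitted \code{drug_model} with at least one nonzero
#'   coefficient.
#' @param predictors samples x p matrix the model applies to.
#' @return named non-negative shares summing to 1 (zero-coefficient
#'   predictors get share 0).
#' @export
factor_contributions <- function(model, predictors) {
  X <- as.matrix(predictors)
  b <- model$coefficients
  if (all(b == 0)) stop("factor_contributions: model has no nonzero coefficients")
  if (!is.null(colnames(X)) && !is.null(names(b)) && all(names(b) %in% colnames(X)))
    X <- X[, names(b), drop = FALSE]
  raw <- colMeans(abs(sweep(X, 2, b, "*")))
  share <- raw / sum(raw[b != 0])
  share[b == 0] <- 0
  share / sum(share)
}

#' Partition samples into predicted-sensitive and predicted-resistant groups
#'
#' Takes the union of the top_n factors by absolute elastic-net coefficient;
#' those with negative coefficients are sensitivity factors (higher loading,
#' lower AUC), positive ones resistance factors. Each sample is assigned by
#' whether its summed loading on the sensitivity factors exceeds that on the
#' resistance factors.
#'
#' @param C samples x k loading matrix (named columns matching the model's
#'   predictors when available).
#' @param model a fitted \code{drug_model}.
#' @param top_n how many top-|coefficient| factors to consider (default 5).
#' @param tie group assigned on exact ties (default \code{"sensitive"}).
#' @return list with \code{group} (named factor "sensitive"/"resistant"),
#'   \code{sensitivity_factors}, \code{resistance_factors}.
#' @export
sensitivity_partition <- function(C, model, top_n = 5,
                                  tie = c("sensitive", "resistant")) {
  tie <- match.arg(tie)
  C <- as.matrix(C)
  b <- model$coefficients
  nz <- which(b != 0)
  if (length(nz) == 0) stop("sensitivity_partition: model has no nonzero coefficients")
  top <- nz[order(-abs(b[nz]))][seq_len(min(top_n, length(nz)))]
  sens <- top[b[top] < 0]; resi <- top[b[top] > 0]
  if (length(sens) == 0 || length(resi) == 0)
    stop("sensitivity_partition: top coefficients are one-sided; partition unavailable")
  if (!is.null(colnames(C)) && !is.null(names(b)) && all(names(b) %in% colnames(C)))
    C <- C[, names(b), drop = FALSE]
  s_sens <- rowSums(C[, sens, drop = FALSE])
  s_resi <- rowSums(C[, resi, drop = FALSE])
  grp <- ifelse(s_sens > s_resi, "sensitive",
                ifelse(s_sens < s_resi, "resistant", tie))
  list(group = stats::setNames(grp, rownames(C)),
       sensitivity_factors = names(b)[sens] %||% sens,
       resistance_factors = names(b)[resi] %||% resi)
}
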