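## Rank selection: scan candidate factor counts, score each fit by AIC and by
## average pairwise factor redundancy (cosine similarity on the Khatri-Rao
## product of gene- and data-type factors), and pick the smallest rank within
## a tolerance band of the AIC minimum subject to a redundancy guardrail.

#' Deterministic initialization from leading singular vectors
#'
#' For each mode, the k leading right singular vectors of that mode's
#' unfolding, taken elementwise absolute, form the initial factor matrix.
#' Deterministic up to the sign convention, which the absolute value resolves.
#' When k exceeds a mode's dimension (typically the layer mode, d < k), the
#' first dim columns are the available singular vectors and the remainder are
#' seeded uniform draws scaled to the mean singular-column norm.
#'
#' @param cube a \code{data_cube} or 3-way array.
#' @param k number of factors.
#' @param seed integer seed used only for padding columns beyond a mode's
#'   dimension.
#' @return list with non-negative factor matrices G, C, D.
#' @export
eigen_init <- function(cube, k, seed = 1L) {
  a <- cube_values(cube)
  dm <- dim(a)
  set.seed(as.integer(seed))
  one_mode <- function(mode, n) {
    Xm <- unfold(a, mode)                 # rows: other modes, cols: this mode
    kk <- min(k, n)
    ## right singular vectors of Xm = eigenvectors of Xm^T Xm (n x n, cheap)
    ev <- eigen(crossprod(Xm), symmetric = TRUE)
    V <- abs(ev$vectors[, seq_len(kk), drop = FALSE])
    if (kk < k) {
      pad <- matrix(stats::runif(n * (k - kk)), n, k - kk)
      pad <- pad * mean(sqrt(colSums(V^2))) / mean(sqrt(colSums(pad^2)))
      V <- cbind(V, pad)
    }
    V
  }
  G <- one_mode("gene", dm[1])
  C <- one_mode("sample", dm[2])
  D <- one_mode("layer", dm[3])
  ## scale so the initial reconstruction matches the cube's Frobenius norm
  rec_norm <- sqrt(sum(model_unfolding(G, C, D, "layer")^2))
  s <- (sqrt(sum(a^2)) / max(rec_norm, MU_EPS))^(1 / 3)
  list(G = G * s, C = C * s, D = D * s)
}

#' Akaike information criterion for a fitted factorization
#'
#' Gaussian profile-likelihood form: AIC = n * log(RSS / n) + 2p, with n the
#' number of cube entries, RSS the unweighted squared residual, and
#' p = k (g + c + d) free factor parameters. Lower is better. Both the
#' n definition and the parameter count are exposed.
#'
#' @param model a \code{won_parafac} fit (or list with G, C, D, scales).
#' @param cube cube to score against; defaults to the model's training cube.
#' @param n_obs,n_par overrides for the entry and parameter counts.
#' @return scalar AIC; -Inf (with a warning) when RSS is numerically zero,
#'   flagging an overfit/saturated model.
#' @export
aic_factorization <- function(model, cube = model$cube, n_obs = NULL, n_par = NULL) {
  a <- cube_values(cube)
  fac <- model_factors(model)
  rss <- sum((cp_reconstruct(fac$G, fac$C, fac$D) - a)^2)
  n <- if (is.null(n_obs)) length(a) else n_obs
  k <- ncol(fac$G)
  p <- if (is.null(n_par)) k * (dim(a)[1] + dim(a)[2] + dim(a)[3]) else n_par
  if (rss <= 0) {
    warning("aic_factorization: zero residual (overfit); returning -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * p
}

#' Average pairwise factor cosine similarity on Y_GD
#'
#' Redundancy measure: the mean cosine similarity over all unordered pairs of
#' columns of the Khatri-Rao product of the gene- and data-type factor
#' matrices. Non-negative because the factors are non-negative. Pairs
#' involving an all-zero column are skipped (and counted in the
#' \code{"skipped"} attribute).
#'
#' @param model a \code{won_parafac} fit (k >= 2).
#' @return scalar in [0, 1].
#' @export
mean_factor_cosine <- function(model) {
  G <- as.matrix(model$G); D <- as.matrix(model$D)
  if (ncol(G) < 2) stop("mean_factor_cosine: need at least 2 factors")
  Y <- khatri_rao(D, G)
  n <- sqrt(colSums(Y^2))
  keep <- n > 0
  Yk <- sweep(Y[, keep, drop = FALSE], 2, n[keep], "/")
  S <- crossprod(Yk)
  m <- sum(keep)
  if (m < 2) stop("mean_factor_cosine: fewer than 2 nonzero factors")
  val <- (sum(S) - m) / (m * (m - 1))
  attr(val, "skipped") <- sum(!keep)
  val
}

#' Scan candidate ranks and choose the number of factors
#'
#' Fits the model at each candidate rank from the deterministic singular-vector
#' initialization, records the weighted objective, AIC and mean factor cosine,
#' and chooses the smallest rank whose AIC lies within a tolerance band of the
#' minimum, subject to the redundancy guardrail
#' \code{mean_cosine <= cosine_threshold} (ignored if no rank satisfies it).
#'
#' @param cube a \code{data_cube} or 3-way array.
#' @param ks candidate ranks; default the coarse grid seq(10, 200, by = 10).
#' @param w orthogonality mixing weight passed to [won_parafac()].
#' @param seed integer seed.
#' @param aic_band relative tolerance band around the minimum AIC (default
#'   0.01 of its magnitude).
#' @param cosine_threshold redundancy guardrail (default 0.5).
#' @param ... further arguments to [won_parafac()] (tol, max_iter, weights).
#' @return An object of class \code{"rank_scan"}: data frame with columns k,
#'   objective, aic, mean_cosine, ok, plus \code{chosen_k} and the per-k error
#'   messages of any failed fits.
#' @export
scan_ranks <- function(cube, ks = seq(10, 200, by = 10), w = 0.1, seed = 1L,
                       aic_band = 0.01, cosine_threshold = 0.5, ...) {
  ks <- sort(unique(as.integer(ks)))
  res <- data.frame(k = ks, objective = NA_real_, aic = NA_real_,
                    mean_cosine = NA_real_, ok = FALSE)
  errors <- list()
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- tryCatch(won_parafac(cube, k = k, w = w, init = "eigen", seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) { errors[[as.character(k)]] <- conditionMessage(fit); next }
    res$objective[i] <- fit$objective
    res$aic[i] <- aic_factorization(fit, cube)
    res$mean_cosine[i] <- if (k >= 2) as.numeric(mean_factor_cosine(fit)) else 0
    res$ok[i] <- TRUE
  }
  okk <- res[res$ok & is.finite(res$aic), , drop = FALSE]
  if (nrow(okk) == 0) stop("scan_ranks: every fit failed")
  amin <- min(okk$aic)
  band <- okk$aic <= amin + aic_band * abs(amin)
  cand <- okk[band, , drop = FALSE]
  guard <- cand$mean_cosine <= cosine_threshold
  if (any(guard)) cand <- cand[guard, , drop = FALSE]
  chosen <- min(cand$k)
  structure(list(table = res, chosen_k = chosen, errors = errors,
                 aic_band = aic_band, cosine_threshold = cosine_threshold),
            class = "rank_scan")
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("Rank scan over %d candidate ranks; chosen k = %d\n",
              nrow(x$table), x$chosen_k))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$errors))
    cat("Failed fits at k =", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}
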