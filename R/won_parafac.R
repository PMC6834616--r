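## Weighted orthogonal non-negative PARAFAC (CP) model.
##
## The cube X (genes x samples x layers) is approximated by a sum of k rank-1
## tensors g_j (x) c_j (x) d_j with all factors non-negative. Fitting proceeds
## by alternating multiplicative updates of the three factor matrices G, C, D,
## each derived from the weighted least-squares objective
##   sum_ij W(i,j) (Y F^T (i,j) - X_(m)(i,j))^2
## on the corresponding mode unfolding. An orthogonality penalty on the gene
## factors (a gradient projected onto the Stiefel manifold G^T G = I) is mixed
## into the gene-mode denominator with weight w in [0, 1]: w = 0 is the plain
## weighted update, w = 1 the fully orthogonality-constrained one.

MU_EPS <- 1e-12

## One multiplicative update of a single factor matrix, on precomputed
## unfoldings. Returns the updated matrix; non-negativity is preserved by
## construction, and entries with vanishing numerator and denominator stay 0.
mu_update <- function(Xm, Wm, G, C, D, mode, w) {
  if (mode == "gene") {
    Y <- khatri_rao(D, C); Fm <- G
  } else if (mode == "sample") {
    Y <- khatri_rao(D, G); Fm <- C
  } else {
    Y <- khatri_rao(C, G); Fm <- D
  }
  num <- crossprod(Wm * Xm, Y)                      # (W (.) X)^T Y
  WR <- t(Wm) * tcrossprod(Fm, Y)                   # W^T (.) (F Y^T)
  if (mode == "gene" && w > 0) {
    den <- (1 - w) * (WR %*% Y) + w * (WR %*% Xm %*% Fm)
  } else {
    den <- WR %*% Y
  }
  Fm * (num / pmax(den, MU_EPS))
}

#' One multiplicative update of one factor matrix
#'
#' Exposes a single alternating-update step: exactly one of G, C or D is
#' replaced by its weighted multiplicative update. For the gene mode the
#' orthogonality-mixed denominator with mixing weight \code{w} is used;
#' sample- and layer-mode updates are the plain weighted updates.
#'
#' @param cube a \code{data_cube} or 3-way array.
#' @param weights a \code{weight_tensor}, a 3-way array of weights, or NULL
#'   for unit weights.
#' @param model list or \code{won_parafac} with factor matrices G, C, D
#'   (raw scale; a normalized model's scales are absorbed into G).
#' @param mode which factor to update: \code{"gene"}, \code{"sample"} or
#'   \code{"layer"}.
#' @param w orthogonality mixing weight in [0, 1] (gene mode only).
#' @return The model with the one factor matrix replaced.
#' @export
update_factor <- function(cube, weights, model, mode = c("gene", "sample", "layer"),
                          w = 0) {
  mode <- match.arg(mode)
  fac <- model_factors(model)
  if (any(!is.finite(fac$G)) || any(!is.finite(fac$C)) || any(!is.finite(fac$D)) ||
      any(fac$G < 0) || any(fac$C < 0) || any(fac$D < 0))
    stop("update_factor: factors must be finite and non-negative")
  Xm <- unfold(cube, mode)
  Wm <- unfold(weight_values(weights, cube), mode)
  upd <- mu_update(Xm, Wm, fac$G, fac$C, fac$D, mode, w)
  slot <- switch(mode, gene = "G", sample = "C", layer = "D")
  model[[slot]] <- upd
  if (!is.null(model$scales)) model$scales <- NULL  # raw scale now
  model
}

## Extract raw-scale factor matrices from a model list or fitted object
## (scales, if present, absorbed into G).
model_factors <- function(model) {
  G <- as.matrix(model$G); C <- as.matrix(model$C); D <- as.matrix(model$D)
  if (!is.null(model$scales)) G <- sweep(G, 2, model$scales, "*")
  list(G = G, C = C, D = D)
}

#' Weighted reconstruction objective
#'
#' Sum over all cube entries of weight times squared residual between the cube
#' and the model reconstruction. The value is identical whichever mode's
#' unfolding is used to evaluate it.
#'
#' @inheritParams update_factor
#' @return non-negative scalar.
#' @export
weighted_objective <- function(cube, weights, model) {
  fac <- model_factors(model)
  Xl <- unfold(cube, "layer")
  Wl <- unfold(weight_values(weights, cube), "layer")
  R <- model_unfolding(fac$G, fac$C, fac$D, "layer") - Xl
  sum(Wl * R * R)
}

#' Fit a weighted orthogonal non-negative PARAFAC model
#'
#' Decomposes a non-negative genes x samples x layers data cube into k
#' non-negative factor triples (gene-factors G, sample-factors C, data-type
#' factors D) by alternating multiplicative updates, with per-layer weights
#' balancing the data types and an orthogonality penalty of strength \code{w}
#' on the gene factors. After convergence the factors are rescaled to unit
#' column norms and sorted by decreasing scale (the product of the three
#' removed norms).
#'
#' @param cube a \code{data_cube} or non-negative 3-way array.
#' @param k number of factors (rank), >= 1.
#' @param w orthogonality mixing weight in [0, 1]; default 0.1.
#' @param weights \code{"layer"} (default: per-layer weights
#'   1/||X_d||_F^2 from [compute_weights()]), \code{"unit"}, or a
#'   \code{weight_tensor} / array.
#' @param init \code{"random"} (seeded uniform factors scaled to the cube's
#'   norm), \code{"eigen"} (absolute leading singular vectors of each mode's
#'   unfolding, see [eigen_init()]), or a model list with G, C, D.
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param max_iter maximum number of full update sweeps (default 500).
#' @param seed integer seed controlling initialization (and layer-mode
#'   eigen-init padding); the run is bit-reproducible given (init, seed).
#' @param update_modes which factor matrices are updated each sweep; the
#'   default updates all three in the order gene, sample, layer. (Cohort
#'   projection onto frozen G and D uses \code{"sample"} only; see
#'   [project_cohort()].)
#' @param normalize pass the result through [normalize_and_sort()] (default
#'   TRUE).
#' @return An object of class \code{"won_parafac"} with components \code{G},
#'   \code{C}, \code{D} (unit-norm columns when normalized), \code{scales},
#'   \code{k}, \code{w}, \code{objective_trace}, \code{converged},
#'   \code{iterations}, \code{seed}, and the training cube.
#' @examples
#' cube <- sim_planted_cube(sim_spec(g = 30, c = 20, d = 3, k_true = 2, seed = 1))
#' fit <- won_parafac(cube$cube, k = 2, w = 0.1, seed = 1)
#' fit
#' @export
won_parafac <- function(cube, k, w = 0.1, weights = c("layer", "unit"),
                        init = "random", tol = 1e-6, max_iter = 500L,
                        seed = 1L, update_modes = c("gene", "sample", "layer"),
                        normalize = TRUE) {
  a <- cube_values(cube)
  stopifnot(k >= 1, w >= 0, w <= 1)
  if (any(a < 0)) stop("won_parafac: cube must be non-negative")
  update_modes <- match.arg(update_modes, several.ok = TRUE)
  wt <- if (inherits(weights, "weight_tensor")) {
    weights
  } else if (is.array(weights)) {
    structure(list(values = weights, layer_weights = NULL), class = "weight_tensor")
  } else {
    weights <- match.arg(weights)
    if (weights == "layer") compute_weights(a) else
      structure(list(values = array(1, dim = dim(a)), layer_weights = rep(1, dim(a)[3])),
                class = "weight_tensor")
  }

  set.seed(as.integer(seed))
  if (is.list(init)) {
    fac <- model_factors(init)
  } else if (identical(init, "eigen")) {
    fac <- model_factors(eigen_init(a, k))
  } else if (identical(init, "random")) {
    dm <- dim(a)
    fac <- list(G = matrix(stats::runif(dm[1] * k), dm[1], k),
                C = matrix(stats::runif(dm[2] * k), dm[2], k),
                D = matrix(stats::runif(dm[3] * k), dm[3], k))
    rec_norm <- sqrt(sum(model_unfolding(fac$G, fac$C, fac$D, "layer")^2))
    s <- (sqrt(sum(a^2)) / max(rec_norm, MU_EPS))^(1 / 3)
    fac <- lapply(fac, `*`, s)
  } else stop("won_parafac: unknown init")
  if (ncol(fac$G) != k) stop("won_parafac: init rank does not match k")

  ## precompute unfoldings of data and weights once
  X <- list(gene = unfold(a, "gene"), sample = unfold(a, "sample"),
            layer = unfold(a, "layer"))
  Wv <- wt$values
  if (!identical(dim(Wv), dim(a))) stop("won_parafac: weight shape mismatch")
  W <- list(gene = unfold(Wv, "gene"), sample = unfold(Wv, "sample"),
            layer = unfold(Wv, "layer"))

  obj <- function(f) {
    R <- model_unfolding(f$G, f$C, f$D, "layer") - X$layer
    sum(W$layer * R * R)
  }
  trace <- numeric(0)
  prev <- obj(fac)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    for (m in update_modes) {
      upd <- mu_update(X[[m]], W[[m]], fac$G, fac$C, fac$D, m, w)
      fac[[switch(m, gene = "G", sample = "C", layer = "D")]] <- upd
    }
    cur <- obj(fac)
    if (!is.finite(cur)) {
      e <- simpleError("won_parafac: non-finite objective (divergence)")
      e$objective_trace <- trace
      stop(e)
    }
    trace <- c(trace, cur)
    if (abs(prev - cur) <= tol * max(prev, MU_EPS)) { converged <- TRUE; break }
    prev <- cur
  }

  ans <- list(G = fac$G, C = fac$C, D = fac$D, scales = NULL,
              k = k, w = w, weights = wt$layer_weights,
              objective = trace[length(trace)], objective_trace = trace,
              converged = converged, iterations = iter,
              seed = as.integer(seed), dims = dim(a),
              gene_ids = dimnames(a)[[1]], sample_ids = dimnames(a)[[2]],
              layer_names = dimnames(a)[[3]],
              cube = a, call = match.call())
  class(ans) <- "won_parafac"
  if (normalize) ans <- normalize_and_sort(ans) else ans$normalized <- FALSE
  ans
}

#' Rescale factor columns to unit norm and sort factors by scale
#'
#' Each factor column of G, C and D is rescaled to unit l2 norm; the per-factor
#' scale is the product of the three removed norms. Factors are sorted by
#' decreasing scale (ties broken stably by original index). All-zero columns
#' get scale 0, sort last and are flagged. The reconstruction
#' sum_j scale_j g_j (x) c_j (x) d_j is unchanged.
#'
#' @param model a \code{won_parafac} fit or list with G, C, D (and optionally
#'   scales already split out).
#' @return The model with unit-norm sorted columns, \code{scales}, and
#'   \code{zero_factors} flags.
#' @export
normalize_and_sort <- function(model) {
  fac <- model_factors(model)
  norm2 <- function(M) sqrt(colSums(M^2))
  gn <- norm2(fac$G); cn <- norm2(fac$C); dn <- norm2(fac$D)
  unitize <- function(M, n) sweep(M, 2, ifelse(n > 0, n, 1), "/")
  G <- unitize(fac$G, gn); C <- unitize(fac$C, cn); D <- unitize(fac$D, dn)
  scales <- gn * cn * dn
  ord <- order(-scales, seq_along(scales))  # stable on ties
  model$G <- G[, ord, drop = FALSE]
  model$C <- C[, ord, drop = FALSE]
  model$D <- D[, ord, drop = FALSE]
  model$scales <- scales[ord]
  model$zero_factors <- which(model$scales == 0)
  model$normalized <- TRUE
  model
}

#' Fraction of variation explained by a model
#'
#' 1 - ||residual||^2 / ||data||^2, over the whole cube, per sample fiber
#' (that sample's genes x layers slice) or per layer slab. Unweighted.
#'
#' @param cube a \code{data_cube} or 3-way array; defaults to the model's
#'   training cube.
#' @param model a \code{won_parafac} fit (or list with G, C, D, scales).
#' @param by \code{"total"}, \code{"sample"} or \code{"layer"}.
#' @return scalar or named per-unit vector of fractions (<= 1); units with
#'   zero data norm are NA.
#' @export
explained_variation <- function(model, cube = model$cube,
                                by = c("total", "sample", "layer")) {
  by <- match.arg(by)
  a <- cube_values(cube)
  fac <- model_factors(model)
  res2 <- (cp_reconstruct(fac$G, fac$C, fac$D) - a)^2
  tot2 <- a^2
  f <- function(r, t) ifelse(t > 0, 1 - r / t, NA_real_)
  switch(by,
    total = f(sum(res2), sum(tot2)),
    sample = {
      v <- f(apply(res2, 2, sum), apply(tot2, 2, sum))
      names(v) <- dimnames(a)[[2]]; v
    },
    layer = {
      v <- f(apply(res2, 3, sum), apply(tot2, 3, sum))
      names(v) <- dimnames(a)[[3]]; v
    })
}

#' Cosine similarity between data-type factor rows
#'
#' Measures how strongly pairs of data types (layers) co-load on the same
#' factors, e.g. copy-number gain with over-expression (cis-effects).
#'
#' @param model a \code{won_parafac} fit.
#' @return layers x layers symmetric matrix; diagonal 1 for nonzero rows;
#'   pairs involving an all-zero row are NA.
#' @export
dt_similarity <- function(model) {
  D <- as.matrix(model$D)
  n <- sqrt(rowSums(D^2))
  S <- tcrossprod(D) / outer(n, n)
  S[n == 0, ] <- NA_real_; S[, n == 0] <- NA_real_
  diag(S)[n > 0] <- 1
  rn <- model$layer_names
  if (!is.null(rn)) dimnames(S) <- list(rn, rn)
  S
}

#' @export
print.won_parafac <- function(x, ...) {
  cat(sprintf("WON-PARAFAC fit: k = %d factors, w = %.3g, %d x %d x %d cube\n",
              x$k, x$w, x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("  %d sweeps, %sconverged; final weighted objective %.6g\n",
              x$iterations, if (x$converged) "" else "NOT ", x$objective))
  cat(sprintf("  explained variation (total): %.3f\n", explained_variation(x)))
  invisible(x)
}

#' @export
summary.won_parafac <- function(object, ...) {
  ev <- explained_variation(object, by = "layer")
  ans <- list(k = object$k, w = object$w, dims = object$dims,
              converged = object$converged, iterations = object$iterations,
              objective = object$objective,
              ev_total = explained_variation(object),
              ev_layer = ev, scales = object$scales,
              dt_similarity = dt_similarity(object))
  class(ans) <- "summary.won_parafac"
  ans
}

#' @export
print.summary.won_parafac <- function(x, ...) {
  cat(sprintf("WON-PARAFAC: k = %d, w = %.3g, cube %d x %d x %d\n",
              x$k, x$w, x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("Total explained variation: %.3f\n", x$ev_total))
  cat("Per-layer explained variation:\n")
  print(round(x$ev_layer, 3))
  cat("Leading factor scales:\n")
  print(round(utils::head(x$scales, 10), 3))
  invisible(x)
}

#' @export
coef.won_parafac <- function(object, mode = c("sample", "gene", "layer", "all"), ...) {
  mode <- match.arg(mode)
  nm <- function(M, ids) { if (!is.null(ids)) rownames(M) <- ids; M }
  G <- nm(object$G, object$gene_ids)
  C <- nm(object$C, object$sample_ids)
  D <- nm(object$D, object$layer_names)
  switch(mode, gene = G, sample = C, layer = D,
         all = list(G = G, C = C, D = D, scales = object$scales))
}

#' @export
fitted.won_parafac <- function(object, ...) {
  fac <- model_factors(object)
  r <- cp_reconstruct(fac$G, fac$C, fac$D)
  dimnames(r) <- list(object$gene_ids, object$sample_ids, object$layer_names)
  r
}

#' @export
residuals.won_parafac <- function(object, ...) {
  object$cube - fitted(object)
}

#' @export
plot.won_parafac <- function(x, which = c("trace", "scales"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$objective_trace), x$objective_trace, type = "l",
                   xlab = "sweep", ylab = "weighted objective",
                   main = "WON-PARAFAC objective trace", ...)
  } else {
    graphics::barplot(x$scales, xlab = "factor", ylab = "scale",
                      main = "Factor scales (decreasing)", ...)
  }
  invisible(x)
}

#' Simulate cubes from a fitted model
#'
#' Draws cubes equal to the model reconstruction plus Gaussian noise, clipped
#' at zero to keep non-negativity.
#'
#' @param object a \code{won_parafac} fit.
#' @param nsim number of cubes.
#' @param seed integer seed.
#' @param noise_sd noise standard deviation (default 0.05 of the cube's RMS
#'   entry).
#' @param ... unused.
#' @return list of \code{data_cube}s.
#' @export
simulate.won_parafac <- function(object, nsim = 1, seed = 1L, noise_sd = NULL, ...) {
  set.seed(as.integer(seed))
  rec <- fitted(object)
  if (is.null(noise_sd)) noise_sd <- 0.05 * sqrt(mean(rec^2))
  lapply(seq_len(nsim), function(i) {
    as_data_cube(pmax(rec + stats::rnorm(length(rec), sd = noise_sd), 0),
                 gene_ids = object$gene_ids %||% paste0("g", seq_len(dim(rec)[1])),
                 sample_ids = object$sample_ids %||% paste0("s", seq_len(dim(rec)[2])),
                 layer_names = object$layer_names %||% paste0("L", seq_len(dim(rec)[3])))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
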