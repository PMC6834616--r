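## Projection of an independent cohort (e.g. patient-derived xenografts)
## onto the gene- and data-type factors learned on cell lines, with a
## permuted-cube baseline, tissue linkage, and embedding-space separation.

#' Project a new cohort onto fixed gene- and data-type factors
#'
#' Freezes G and D from a fitted model and optimizes only the new cohort's
#' sample-factor matrix P by the sample-mode multiplicative update, minimizing
#' the (unweighted) Frobenius objective ||Y_GD P^T - X_(P)||^2. The new cube
#' must share the model's gene and layer axes, order included, and should be
#' preprocessed with cohort-internal statistics.
#'
#' @param model a \code{won_parafac} fit.
#' @param new_cube a \code{data_cube} (or 3-way array) for the new cohort.
#' @param tol,max_iter convergence controls (defaults 1e-6, 500).
#' @param seed integer seed for the P initialization (seeded uniform scaled to
#'   the cohort's norm).
#' @param weights optional \code{weight_tensor}/array; default NULL = unit
#'   weights (the plain Frobenius projection objective).
#' @return An object of class \code{"cohort_projection"}: \code{P} (samples x
#'   k, non-negative; factor scales absorbed), per-sample and total explained
#'   variation, objective trace, convergence flag and provenance.
#' @export
project_cohort <- function(model, new_cube, tol = 1e-6, max_iter = 500L,
                           seed = 1L, weights = NULL) {
  stopifnot(inherits(model, "won_parafac"))
  a <- cube_values(new_cube)
  if (a_dim_mismatch(model, a))
    stop("project_cohort: gene/layer axes do not match the model (no silent subsetting)")
  nid <- dimnames(a)[[1]]
  if (!is.null(nid) && !is.null(model$gene_ids) && !identical(nid, model$gene_ids))
    stop("project_cohort: gene identifiers differ from the model's (order included)")
  lid <- dimnames(a)[[3]]
  if (!is.null(lid) && !is.null(model$layer_names) && !identical(lid, model$layer_names))
    stop("project_cohort: layer names differ from the model's (order included)")

  k <- model$k
  nsamp <- dim(a)[2]
  set.seed(as.integer(seed))
  P0 <- matrix(stats::runif(nsamp * k), nsamp, k)
  G <- as.matrix(model$G); D <- as.matrix(model$D)  # unit-norm; P absorbs scale
  rec_norm <- sqrt(sum(model_unfolding(G, P0, D, "layer")^2))
  P0 <- P0 * sqrt(sum(a^2)) / max(rec_norm, MU_EPS)

  wt <- if (is.null(weights)) array(1, dim = dim(a)) else weight_values(weights, a)
  Xc <- unfold(a, "sample"); Wc <- unfold(wt, "sample")
  Xl <- unfold(a, "layer"); Wl <- unfold(wt, "layer")
  obj <- function(P) {
    R <- model_unfolding(G, P, D, "layer") - Xl
    sum(Wl * R * R)
  }
  P <- P0
  trace <- numeric(0)
  prev <- obj(P)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    P <- mu_update(Xc, Wc, G, P, D, "sample", w = 0)
    cur <- obj(P)
    trace <- c(trace, cur)
    if (abs(prev - cur) <= tol * max(prev, MU_EPS)) { converged <- TRUE; break }
    prev <- cur
  }
  rownames(P) <- dimnames(a)[[2]]
  res2 <- (cp_reconstruct(G, P, D) - a)^2
  tot2 <- a^2
  ev_sample <- ifelse(apply(tot2, 2, sum) > 0,
                      1 - apply(res2, 2, sum) / apply(tot2, 2, sum), NA_real_)
  names(ev_sample) <- dimnames(a)[[2]]
  structure(list(P = P, ev_sample = ev_sample,
                 ev_total = 1 - sum(res2) / sum(tot2),
                 objective_trace = trace, converged = converged,
                 iterations = iters, seed = as.integer(seed),
                 model_k = k, model_w = model$w),
            class = "cohort_projection")
}

a_dim_mismatch <- function(model, a) {
  dm <- dim(a)
  dm[1] != model$dims[1] || dm[3] != model$dims[3]
}

#' @export
print.cohort_projection <- function(x, ...) {
  cat(sprintf("cohort_projection: %d samples on %d frozen factors\n",
              nrow(x$P), x$model_k))
  cat(sprintf("  %d sweeps, %sconverged; total explained variation %.3f\n",
              x$iterations, if (x$converged) "" else "NOT ", x$ev_total))
  invisible(x)
}

#' @rdname project_cohort
#' @param object a \code{won_parafac} fit.
#' @param newdata the new cohort cube.
#' @param ... passed to [project_cohort()].
#' @export
predict.won_parafac <- function(object, newdata, ...) {
  project_cohort(object, newdata, ...)
}

#' Explained variation of a projection under a permuted-cube baseline
#'
#' Destroys the cohort's structure by independently permuting gene and sample
#' indices within each layer, projects each permuted cube, and returns the
#' per-sample explained variation under every permutation.
#'
#' @param model a \code{won_parafac} fit.
#' @param new_cube the cohort cube.
#' @param n_perm number of permutations (default 1).
#' @param seed integer seed; permutation b uses seed + b - 1.
#' @param ... passed to [project_cohort()] (tol, max_iter).
#' @return n_perm x samples matrix of explained-variation values.
#' @export
permuted_baseline <- function(model, new_cube, n_perm = 1, seed = 1L, ...) {
  a <- cube_values(new_cube)
  dm <- dim(a)
  out <- matrix(NA_real_, n_perm, dm[2])
  for (b in seq_len(n_perm)) {
    set.seed(as.integer(seed) + b - 1L)
    pa <- a
    for (l in seq_len(dm[3])) {
      pg <- sample.int(dm[1]); ps <- sample.int(dm[2])
      pa[, , l] <- a[pg, ps, l]
    }
    pr <- project_cohort(model, pa, seed = as.integer(seed) + b - 1L, ...)
    out[b, ] <- pr$ev_sample
  }
  colnames(out) <- dimnames(a)[[2]]
  out
}

#' Association of projected samples with tissue-linked factor sets
#'
#' For each sample i and tissue-linked factor set T:
#' sum_{k in T} P(i, k) / sum_l P(i, l) - close to 1 when the sample's
#' variation is mostly captured by T's factors.
#'
#' @param P samples x k non-negative loading matrix (e.g. from
#'   [project_cohort()]).
#' @param factor_sets named list mapping each tissue to its factor indices.
#' @return samples x tissues matrix of values in [0, 1]; rows with zero total
#'   loading are NA.
#' @export
tissue_association <- function(P, factor_sets) {
  P <- as.matrix(P)
  tot <- rowSums(P)
  out <- vapply(factor_sets, function(T) {
    v <- rowSums(P[, T, drop = FALSE]) / tot
    v[tot == 0] <- NA_real_
    v
  }, numeric(nrow(P)))
  rownames(out) <- rownames(P)
  out
}

#' Fisher criterion for two groups of embedded points
#'
#' Squared Euclidean distance between the two group mean vectors divided by
#' the sum of the two groups' total variances (trace of the per-group
#' population covariance). Invariant under rotation, translation and uniform
#' scaling of the coordinates.
#'
#' @param points n x p coordinate matrix (p = 2 for a 2-D embedding) or a
#'   vector for 1-D.
#' @param labels two-level grouping of the rows.
#' @return non-negative scalar; +Inf (with a warning) when both variances are
#'   zero but the means differ.
#' @export
fisher_criterion <- function(points, labels) {
  X <- as.matrix(points)
  labels <- as.factor(labels)
  lv <- levels(droplevels(labels))
  if (length(lv) != 2) stop("fisher_criterion: need exactly two groups")
  i1 <- labels == lv[1]; i2 <- labels == lv[2]
  if (!any(i1) || !any(i2)) stop("fisher_criterion: both groups must be non-empty")
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  popvar <- function(M) sum(colMeans(sweep(M, 2, colMeans(M))^2))
  s1 <- popvar(X[i1, , drop = FALSE]); s2 <- popvar(X[i2, , drop = FALSE])
  num <- sum((m1 - m2)^2)
  if (s1 + s2 == 0) {
    if (num == 0) return(0)
    warning("fisher_criterion: zero within-group variance with distinct means")
    return(Inf)
  }
  num / (s1 + s2)
}

#' Seeded random 2-D linear projection
#'
#' A stochastic linear embedding satisfying the contract required by
#' [embedding_separation()]: deterministic given the seed, different across
#' seeds. Columns are projected onto two Gaussian random directions scaled by
#' 1/sqrt(p). Any embedding function with signature (X, seed) -> n x 2 can be
#' substituted (e.g. a t-SNE wrapper).
#'
#' @param X samples x p feature matrix.
#' @param seed integer seed.
#' @param ndim embedding dimension (default 2).
#' @return n x ndim coordinate matrix.
#' @export
random_projection_embedding <- function(X, seed = 1L, ndim = 2) {
  X <- as.matrix(X)
  set.seed(as.integer(seed))
  X %*% matrix(stats::rnorm(ncol(X) * ndim), ncol(X), ndim) / sqrt(ncol(X))
}

#' Cohort separation in embedding space, per group, over repeated embeddings
#'
#' For each named feature space (e.g. raw features vs factor loadings), each
#' repeat generates a fresh seeded 2-D embedding of all samples and measures
#' the Fisher criterion between the two cohorts within each group (e.g.
#' tissue type). The full distribution over repeats is returned.
#'
#' @param features_by_space named list of samples x p matrices over the same
#'   samples in the same order (e.g. \code{list(raw = ..., factor = ...)}).
#' @param cohort two-level cohort label per sample (e.g. cell line vs PDX).
#' @param groups group label per sample (e.g. tissue type).
#' @param n_repeats number of embeddings (default 100).
#' @param seed integer seed; repeat r uses seed + r - 1.
#' @param embed_fun embedding function (X, seed) -> n x 2; default
#'   [random_projection_embedding()].
#' @return data frame with columns repeat_id, space, group, fisher; groups
#'   absent from either cohort are skipped (attribute \code{"skipped"}).
#' @export
embedding_separation <- function(features_by_space, cohort, groups,
                                 n_repeats = 100, seed = 1L,
                                 embed_fun = random_projection_embedding) {
  stopifnot(is.list(features_by_space), !is.null(names(features_by_space)))
  cohort <- as.factor(cohort); groups <- as.character(groups)
  n <- length(cohort)
  ok_groups <- Filter(function(g) {
    idx <- groups == g
    length(unique(cohort[idx])) == 2
  }, unique(groups))
  skipped <- setdiff(unique(groups), ok_groups)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    for (sp in names(features_by_space)) {
      X <- as.matrix(features_by_space[[sp]])
      if (nrow(X) != n) stop("embedding_separation: feature rows must match labels")
      emb <- embed_fun(X, seed = as.integer(seed) + r - 1L)
      for (g in ok_groups) {
        idx <- groups == g
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = r, space = sp, group = g,
          fisher = fisher_criterion(emb[idx, , drop = FALSE],
                                    droplevels(cohort[idx])))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(repeat_id = integer(0), space = character(0),
               group = character(0), fisher = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Correlate cohort responses with drug-model predictions on projected factors
#'
#' Predicts each mapped compound's AUC from the cohort's projected loadings P
#' via its fitted elastic-net model and correlates the prediction with the
#' cohort's own response readout (e.g. best average response) over the shared
#' samples; two-sided test per pair, BH FDR across pairs.
#'
#' @param drug_models named list of \code{drug_model}s (names = compound ids).
#' @param P cohort samples x k loading matrix.
#' @param response_map data frame with columns \code{model_compound} and
#'   \code{cohort_treatment}.
#' @param cohort_response named per-sample response, or a samples x treatments
#'   matrix/data frame.
#' @return data frame (model_compound, cohort_treatment, r, p, fdr, n);
#'   unmapped compounds are skipped with a reason attribute.
#' @export
translate_predictions <- function(drug_models, P, response_map, cohort_response) {
  if (nrow(response_map) == 0) {
    warning("translate_predictions: empty mapping")
    return(data.frame(model_compound = character(0), cohort_treatment = character(0),
                      r = numeric(0), p = numeric(0), fdr = numeric(0), n = integer(0)))
  }
  P <- as.matrix(P)
  get_resp <- function(tr) {
    if (is.matrix(cohort_response) || is.data.frame(cohort_response)) {
      if (!tr %in% colnames(cohort_response)) return(NULL)
      stats::setNames(as.numeric(cohort_response[, tr]), rownames(cohort_response))
    } else cohort_response
  }
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(response_map))) {
    mc <- as.character(response_map$model_compound[i])
    tr <- as.character(response_map$cohort_treatment[i])
    if (!mc %in% names(drug_models)) {
      skipped <- c(skipped, sprintf("%s: no fitted drug model", mc)); next
    }
    resp <- get_resp(tr)
    if (is.null(resp)) {
      skipped <- c(skipped, sprintf("%s: treatment absent from cohort response", tr)); next
    }
    pred <- predict(drug_models[[mc]], P)
    common <- if (!is.null(names(resp)) && !is.null(rownames(P)))
      intersect(rownames(P), names(resp)) else seq_along(pred)
    x <- pred[common]; y <- resp[common]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) { skipped <- c(skipped, sprintf("%s->%s: <3 shared samples", mc, tr)); next }
    ct <- stats::cor.test(x[ok], y[ok])
    rows[[length(rows) + 1L]] <- data.frame(model_compound = mc, cohort_treatment = tr,
                                            r = unname(ct$estimate), p = ct$p.value,
                                            n = sum(ok))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model_compound = character(0), cohort_treatment = character(0),
               r = numeric(0), p = numeric(0), n = integer(0))
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("model_compound", "cohort_treatment", "r", "p", "fdr", "n")]
  attr(out, "skipped") <- skipped
  out
}
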