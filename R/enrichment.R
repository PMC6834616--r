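## Factor annotation: cell-set enrichment (CSEA) of sample categories on
## factor loadings, and gene-set enrichment (GSEA) on per-gene regression
## coefficients of expression against factor loadings.

#' Cell set enrichment analysis of one factor
#'
#' Tests whether a sample category (e.g. a tissue type) is enriched among the
#' samples with high loadings on a factor. For a category T of size n_T the
#' enrichment score is
#' \deqn{ES = \sqrt{n_T} \, \frac{\sum_{i \in T} (c_i - m)}{n_T \, \sigma}}
#' where m and sigma are the mean and (population) standard deviation of all
#' loadings. Under random category membership ES is approximately standard
#' normal, so a right-tailed normal test gives p-values, followed by
#' Benjamini-Hochberg FDR across categories.
#'
#' @param loadings named non-negative per-sample loadings of one factor.
#' @param annotation sample categories: a named character vector, or a data
#'   frame with columns \code{sample_id} and \code{category}.
#' @param n_convention \code{"category"} (default: the score above, calibrated
#'   to N(0,1)) or \code{"all"} (the literal variant with n = total sample
#'   count inside the square root and denominator).
#' @param fdr_threshold categories at FDR below this are flagged significant
#'   (default 0.2).
#' @return data frame with columns category, n, es, p, fdr, significant;
#'   attribute \code{"dropped"} lists annotated samples absent from the
#'   loadings.
#' @export
csea <- function(loadings, annotation, n_convention = c("category", "all"),
                 fdr_threshold = 0.2) {
  n_convention <- match.arg(n_convention)
  ann <- normalize_annotation(annotation)
  if (is.null(names(loadings)))
    stop("csea: loadings must be named by sample")
  dropped <- setdiff(names(ann), names(loadings))
  ann <- ann[names(ann) %in% names(loadings)]
  if (length(unique(ann)) < 2) stop("csea: need at least 2 categories")
  c_all <- loadings[names(ann)]
  n <- length(c_all)
  m <- mean(c_all)
  sg <- sqrt(mean((c_all - m)^2))  # population SD
  if (sg == 0) stop("csea: degenerate factor (zero loading variance)")
  cats <- sort(unique(ann))
  es <- vapply(cats, function(ct) {
    idx <- ann == ct
    nt <- sum(idx)
    if (nt == 0) return(NA_real_)
    if (n_convention == "category") {
      sqrt(nt) * sum(c_all[idx] - m) / (nt * sg)
    } else {
      sqrt(n) * sum(c_all[idx] - m) / (n * sg)
    }
  }, 0)
  keep <- !is.na(es)
  p <- stats::pnorm(es[keep], lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(category = cats[keep],
                    n = as.integer(table(ann)[cats[keep]]),
                    es = es[keep], p = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

normalize_annotation <- function(annotation) {
  if (is.data.frame(annotation)) {
    if (!all(c("sample_id", "category") %in% names(annotation)))
      stop("annotation data frame needs columns sample_id and category")
    stats::setNames(as.character(annotation$category),
                    as.character(annotation$sample_id))
  } else {
    if (is.null(names(annotation))) stop("annotation vector must be named by sample")
    stats::setNames(as.character(annotation), names(annotation))
  }
}

#' CSEA across all factors of a fitted model
#'
#' @param model a \code{won_parafac} fit.
#' @param annotation see [csea()].
#' @param ... passed to [csea()].
#' @return data frame with a leading \code{factor} column stacking the per-
#'   factor CSEA tables; FDR is computed within each factor.
#' @export
csea_all <- function(model, annotation, ...) {
  C <- coef(model, "sample")
  do.call(rbind, lapply(seq_len(ncol(C)), function(j) {
    tab <- csea(stats::setNames(C[, j], rownames(C)), annotation, ...)
    cbind(factor = j, tab)
  }))
}

#' Regress every gene's expression on the factor loadings
#'
#' Per gene, an ordinary least-squares fit of that gene's expression on all k
#' sample-factor loadings jointly (plus an intercept); returns the k slope
#' coefficients per gene. With \code{simple = TRUE}, k univariate slopes are
#' computed instead (one simple regression per factor).
#'
#' @param expression genes x samples matrix (standardized expression; the gene
#'   universe may be wider than the cube's panel).
#' @param C samples x k loading matrix, samples aligned with the expression
#'   columns.
#' @param simple use per-factor univariate slopes instead of the joint fit.
#' @param ridge tiny ridge penalty used only as a fallback when the joint
#'   design is numerically rank-deficient (logged via a warning).
#' @return genes x k coefficient matrix.
#' @export
regress_expression_on_factors <- function(expression, C, simple = FALSE,
                                          ridge = 1e-8) {
  E <- as.matrix(expression); C <- as.matrix(C)
  if (ncol(E) != nrow(C))
    stop("regress_expression_on_factors: sample counts differ")
  k <- ncol(C)
  if (!simple && k >= nrow(C))
    stop("regress_expression_on_factors: need k < number of samples")
  if (simple) {
    Cc <- sweep(C, 2, colMeans(C))
    Ec <- E - rowMeans(E)
    B <- (Ec %*% Cc) / matrix(colSums(Cc^2), nrow(E), k, byrow = TRUE)
  } else {
    X <- cbind(1, C)
    XtX <- crossprod(X)
    sol <- tryCatch(solve(XtX, t(X)), error = function(e) NULL)
    if (is.null(sol)) {
      warning("regress_expression_on_factors: rank-deficient design; ridge fallback")
      sol <- solve(XtX + diag(ridge, ncol(X)), t(X))
    }
    B <- E %*% t(sol)      # genes x (k+1)
    B <- B[, -1, drop = FALSE]
  }
  dimnames(B) <- list(rownames(E), colnames(C))
  B
}

#' Weighted Kolmogorov-Smirnov enrichment score of one gene set
#'
#' The running-sum statistic of the original GSEA with weight exponent
#' \code{p} (default 1): genes are ranked by decreasing statistic, hits
#' increment the running sum proportionally to |stat|^p, misses decrement it
#' uniformly; the ES is the extremum of the running sum.
#'
#' @param stats named per-gene statistics (e.g. regression coefficients).
#' @param set character vector of member gene identifiers.
#' @param p weight exponent (default 1; \code{p = 0} gives the unweighted KS
#'   form).
#' @return signed scalar ES.
#' @export
gsea_es <- function(stats, set, p = 1) {
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  hit <- names(s) %in% set
  es_sorted(s, hit, p)
}

## ES on an already-decreasing-sorted statistic and a logical hit mask.
es_sorted <- function(s, hit, p) {
  nh <- sum(hit)
  if (nh == 0 || nh == length(s)) stop("gsea_es: set is empty or the whole universe")
  wts <- abs(s)^p
  phit <- cumsum(ifelse(hit, wts, 0)) / sum(wts[hit])
  pmiss <- cumsum(!hit) / (length(s) - nh)
  run <- phit - pmiss
  run[which.max(abs(run))]
}

#' Gene set enrichment analysis of one factor's regression coefficients
#'
#' Ranks the gene universe by the per-gene coefficient of expression regressed
#' on the chosen factor, scores each gene set with the weighted KS enrichment
#' score, and builds the null distribution by permuting the samples of the
#' expression matrix and propagating each permutation through the regression.
#' Normalized ES (NES) divides each ES by the mean |null ES| of its sign for
#' that set; FDR is computed from the pooled signed null (positive and
#' negative sides separately, as in the original GSEA).
#'
#' @param expression genes x samples matrix.
#' @param C samples x k loading matrix.
#' @param factor column index (or name) of the factor to test.
#' @param sets named list of gene-identifier vectors (e.g. from [read_gmt()]).
#' @param n_perm number of sample permutations for the null (default 1000).
#' @param seed integer seed for the permutations.
#' @param min_size sets with fewer members in the universe are skipped
#'   (default 5).
#' @param fdr_threshold sets at FDR below this are flagged (default 0.2).
#' @param weight_p KS weight exponent (default 1).
#' @param simple passed to [regress_expression_on_factors()].
#' @return data frame with columns set, size, es, nes, p, fdr, significant;
#'   attribute \code{"skipped"} names sets below \code{min_size}.
#' @export
gsea <- function(expression, C, factor = 1, sets, n_perm = 1000, seed = 1L,
                 min_size = 5, fdr_threshold = 0.2, weight_p = 1,
                 simple = FALSE) {
  if (n_perm < 100) stop("gsea: n_perm must be >= 100")
  E <- as.matrix(expression); C <- as.matrix(C)
  universe <- rownames(E)
  if (is.null(universe)) stop("gsea: expression needs gene rownames")
  sets0 <- lapply(sets, intersect, universe)
  sizes <- lengths(sets0)
  skipped <- names(sets0)[sizes < min_size | sizes >= length(universe)]
  sets0 <- sets0[!(names(sets0) %in% skipped)]
  if (length(sets0) == 0) stop("gsea: no sets pass the size filter")

  B <- regress_expression_on_factors(E, C, simple = simple)
  j <- if (is.character(factor)) match(factor, colnames(B)) else as.integer(factor)
  obs_stat <- stats::setNames(B[, j], universe)

  ## precompute set membership masks over the universe; each scoring pass
  ## then sorts the statistic once and scores every set on the shared order
  masks <- lapply(sets0, function(st) universe %in% st)
  score_all <- function(st) {
    ord <- order(st, decreasing = TRUE)
    s <- st[ord]
    vapply(masks, function(m) es_sorted(s, m[ord], weight_p), 0)
  }
  es_obs <- score_all(obs_stat)

  ## hat vector: obs_stat = E %*% h; a sample permutation of E is equivalent
  ## to permuting h, so each null draw is one matrix-vector product.
  h <- hat_vector(C, j, simple = simple)
  set.seed(as.integer(seed))
  nset <- length(sets0)
  null_es <- matrix(NA_real_, n_perm, nset)
  nsamp <- ncol(E)
  for (b in seq_len(n_perm)) {
    hs <- h[sample.int(nsamp)]
    null_es[b, ] <- score_all(as.numeric(E %*% hs))
  }

  nes_of <- function(es, null_col) {
    mp <- mean(null_col[null_col > 0]); mn <- mean(-null_col[null_col < 0])
    ifelse(es >= 0, es / ifelse(is.finite(mp) && mp > 0, mp, NA_real_),
                    es / ifelse(is.finite(mn) && mn > 0, mn, NA_real_))
  }
  nes_obs <- vapply(seq_len(nset), function(i) nes_of(es_obs[i], null_es[, i]), 0)
  null_nes <- vapply(seq_len(nset), function(i) nes_of(null_es[, i], null_es[, i]),
                     numeric(n_perm))
  pval <- vapply(seq_len(nset), function(i) {
    nc <- null_es[, i]
    if (es_obs[i] >= 0) {
      pos <- nc[nc >= 0]; if (!length(pos)) return(1 / (n_perm + 1))
      (sum(pos >= es_obs[i]) + 1) / (length(pos) + 1)
    } else {
      neg <- nc[nc <= 0]; if (!length(neg)) return(1 / (n_perm + 1))
      (sum(neg <= es_obs[i]) + 1) / (length(neg) + 1)
    }
  }, 0)
  pool <- as.numeric(null_nes)
  fdr <- vapply(seq_len(nset), function(i) {
    x <- nes_obs[i]
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- mean(pool >= x, na.rm = TRUE) /
        max(mean(pool >= 0, na.rm = TRUE), .Machine$double.eps)
      den <- mean(nes_obs >= x, na.rm = TRUE) /
        max(mean(nes_obs >= 0, na.rm = TRUE), .Machine$double.eps)
    } else {
      num <- mean(pool <= x, na.rm = TRUE) /
        max(mean(pool <= 0, na.rm = TRUE), .Machine$double.eps)
      den <- mean(nes_obs <= x, na.rm = TRUE) /
        max(mean(nes_obs <= 0, na.rm = TRUE), .Machine$double.eps)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)
  out <- data.frame(set = names(sets0), size = lengths(sets0),
                    es = es_obs, nes = nes_obs, p = pval, fdr = fdr,
                    significant = !is.na(fdr) & fdr < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

## Column j of the OLS hat matrix X (X'X)^-1 restricted to the factor slopes,
## as an n-vector h with coef_j(gene) = E[gene, ] %*% h.
hat_vector <- function(C, j, simple = FALSE) {
  if (simple) {
    cc <- C[, j] - mean(C[, j])
    cc / sum(cc^2)
  } else {
    X <- cbind(1, C)
    H <- X %*% solve(crossprod(X))
    H[, j + 1]
  }
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member gene
#' identifiers. Uses fgsea's reader when available.
#'
#' @param path file path.
#' @return named list of gene-identifier vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}

#' Export significant factor-term associations as an edge list
#'
#' Plumbing for downstream network viewers: stacks significant rows of
#' enrichment/drug tables into (factor, term, type, score) edges.
#'
#' @param ... named data frames with columns factor, a term column
#'   (category/set/compound), and a score column (es/nes/coefficient), already
#'   filtered or carrying a logical \code{significant} column.
#' @return data frame with columns factor, term, type, score.
#' @export
association_edges <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    stop("association_edges: arguments must be named by association type")
  do.call(rbind, lapply(names(tabs), function(nm) {
    t <- tabs[[nm]]
    if ("significant" %in% names(t)) t <- t[t$significant, , drop = FALSE]
    term_col <- intersect(c("category", "set", "compound", "term"), names(t))[1]
    score_col <- intersect(c("nes", "es", "coefficient", "score"), names(t))[1]
    if (nrow(t) == 0)
      return(data.frame(factor = integer(0), term = character(0),
                        type = character(0), score = numeric(0)))
    data.frame(factor = t$factor, term = t[[term_col]], type = nm,
               score = t[[score_col]], row.names = NULL)
  }))
}
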