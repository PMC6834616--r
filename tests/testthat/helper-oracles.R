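# Independent straight-line oracles used across tests: explicit-loop
# unfoldings, Kronecker-based Khatri-Rao, literal transcriptions of the
# multiplicative update rules, and a triple-loop weighted objective.
# These deliberately avoid the package's unfold()/khatri_rao()/mu paths.

oracle_unfold <- function(a, mode) {
  dm <- dim(a)
  g <- dm[1]; cc <- dm[2]; d <- dm[3]
  if (mode == "gene") {          # (c*d) x g, sample fastest, layer slowest
    m <- matrix(0, cc * d, g)
    for (id in 1:d) for (ic in 1:cc) m[(id - 1) * cc + ic, ] <- a[, ic, id]
  } else if (mode == "sample") { # (g*d) x c, gene fastest, layer slowest
    m <- matrix(0, g * d, cc)
    for (id in 1:d) for (ig in 1:g) m[(id - 1) * g + ig, ] <- a[ig, , id]
  } else {                       # (g*c) x d, gene fastest, sample slowest
    m <- matrix(0, g * cc, d)
    for (ic in 1:cc) for (ig in 1:g) m[(ic - 1) * g + ig, ] <- a[ig, ic, ]
  }
  m
}

oracle_kr <- function(A, B) {
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (j in seq_len(ncol(A))) out[, j] <- kronecker(A[, j], B[, j])
  out
}

# Literal gene-mode multiplicative update: w = 0 the plain weighted rule,
# w = 1 the orthogonality-constrained rule, 0 < w < 1 the mixed denominator.
oracle_update_gene <- function(a, wt, G, C, D, w) {
  Xg <- oracle_unfold(a, "gene")
  Wg <- oracle_unfold(wt, "gene")
  Ycd <- oracle_kr(D, C)
  num <- t(Wg * Xg) %*% Ycd
  WR <- t(Wg) * (G %*% t(Ycd))
  den <- (1 - w) * (WR %*% Ycd) + w * (WR %*% Xg %*% G)
  G * num / den
}

oracle_update_plain <- function(a, wt, G, C, D, mode) {
  if (mode == "sample") {
    Xm <- oracle_unfold(a, "sample"); Wm <- oracle_unfold(wt, "sample")
    Y <- oracle_kr(D, G); Fm <- C
  } else {
    Xm <- oracle_unfold(a, "layer"); Wm <- oracle_unfold(wt, "layer")
    Y <- oracle_kr(C, G); Fm <- D
  }
  num <- t(Wm * Xm) %*% Y
  den <- (t(Wm) * (Fm %*% t(Y))) %*% Y
  Fm * num / den
}

oracle_objective <- function(a, wt, G, C, D) {
  dm <- dim(a)
  tot <- 0
  for (ig in 1:dm[1]) for (ic in 1:dm[2]) for (id in 1:dm[3]) {
    rec <- sum(G[ig, ] * C[ic, ] * D[id, ])
    tot <- tot + wt[ig, ic, id] * (rec - a[ig, ic, id])^2
  }
  tot
}

# small strictly-positive random cube + factor triple
rand_cube <- function(g, c, d, seed = 1) {
  set.seed(seed)
  array(runif(g * c * d, 0.1, 1), dim = c(g, c, d))
}

rand_factors <- function(g, c, d, k, seed = 1, min = 0.1) {
  set.seed(seed)
  list(G = matrix(runif(g * k, min, 1), g, k),
       C = matrix(runif(c * k, min, 1), c, k),
       D = matrix(runif(d * k, min, 1), d, k))
}

unit_weights <- function(a) array(1, dim = dim(a))

# wrap planted truth factors as a fitted model (few sweeps from the truth on
# the noiseless cube, then normalized), for projection tests
model_from_truth <- function(planted, w = 0) {
  won_parafac(planted$cube, k = planted$spec$k_true, w = w, weights = "unit",
              init = planted$truth, tol = 1e-12, max_iter = 3,
              seed = planted$spec$seed)
}
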