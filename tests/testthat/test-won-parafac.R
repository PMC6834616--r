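# Multiplicative updates, weighted objective, normalization and diagnostics
# of the core factorization.

test_that("one factor update matches the literal formula oracles in every mode", {
  a <- rand_cube(4, 3, 2, seed = 21)
  f <- rand_factors(4, 3, 2, k = 2, seed = 22)
  wt <- compute_weights(a)
  for (w in c(0, 0.1, 1)) {
    upd <- update_factor(a, wt, f, "gene", w = w)
    expect_equal(upd$G, oracle_update_gene(a, wt$values, f$G, f$C, f$D, w),
                 tolerance = 1e-12)
  }
  expect_equal(update_factor(a, wt, f, "sample")$C,
               oracle_update_plain(a, wt$values, f$G, f$C, f$D, "sample"),
               tolerance = 1e-12)
  expect_equal(update_factor(a, wt, f, "layer")$D,
               oracle_update_plain(a, wt$values, f$G, f$C, f$D, "layer"),
               tolerance = 1e-12)
  bad <- f; bad$G[1, 1] <- -1
  expect_error(update_factor(a, wt, bad, "gene"), "non-negative")
})

test_that("a zero-residual model is a fixed point of the w = 0 update", {
  f <- rand_factors(5, 4, 3, k = 2, seed = 31)
  a <- wonparafac:::cp_reconstruct(f$G, f$C, f$D)
  for (m in c("gene", "sample", "layer")) {
    upd <- update_factor(a, NULL, f, m, w = 0)
    expect_equal(upd[[switch(m, gene = "G", sample = "C", layer = "D")]],
                 f[[switch(m, gene = "G", sample = "C", layer = "D")]],
                 tolerance = 1e-10)
  }
})

test_that("updates preserve non-negativity exactly", {
  a <- rand_cube(6, 5, 3, seed = 41)
  f <- rand_factors(6, 5, 3, k = 3, seed = 42, min = 0)
  wt <- compute_weights(a)
  for (m in c("gene", "sample", "layer")) {
    f <- update_factor(a, wt, f, m, w = 0.1)
    expect_true(all(f$G >= 0) && all(f$C >= 0) && all(f$D >= 0))
  }
})

test_that("weighted objective equals the triple-loop oracle and reduces to SSR", {
  a <- rand_cube(4, 3, 2, seed = 51)
  f <- rand_factors(4, 3, 2, k = 2, seed = 52)
  wt <- compute_weights(a)
  expect_equal(weighted_objective(a, wt, f),
               oracle_objective(a, wt$values, f$G, f$C, f$D), tolerance = 1e-12)
  # unit weights: plain sum of squared residuals
  expect_equal(weighted_objective(a, NULL, f),
               sum((wonparafac:::cp_reconstruct(f$G, f$C, f$D) - a)^2),
               tolerance = 1e-12)
  # zero residual -> 0
  rec <- wonparafac:::cp_reconstruct(f$G, f$C, f$D)
  expect_equal(weighted_objective(rec, wt, f), 0, tolerance = 1e-20)
})

test_that("the objective is non-increasing over sweeps for w in {0, 0.1}", {
  for (seed in 1:3) {
    a <- rand_cube(12, 9, 4, seed = seed)
    for (w in c(0, 0.1)) {
      fit <- won_parafac(a, k = 3, w = w, seed = seed, tol = 0, max_iter = 60)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) <= 1e-8 * pmax(head(tr, -1), 1e-12)),
                  label = sprintf("monotone trace (seed %d, w %.1f)", seed, w))
    }
  }
})

test_that("normalize_and_sort rescales, sorts, flags and preserves the reconstruction", {
  # single factor with norms (2, 3, 4) -> scale 24
  m1 <- list(G = matrix(c(2, 0)), C = matrix(c(0, 3, 0)), D = matrix(c(0, 0, 4)))
  n1 <- normalize_and_sort(m1)
  expect_equal(n1$scales, 24)
  expect_equal(sqrt(colSums(n1$G^2)), 1)
  # multi-factor: sorted scales, reconstruction unchanged, zero factor flagged
  f <- rand_factors(5, 4, 3, k = 3, seed = 61)
  f$G[, 3] <- 0
  before <- wonparafac:::cp_reconstruct(f$G, f$C, f$D)
  nf <- normalize_and_sort(f)
  expect_true(all(diff(nf$scales) <= 0))
  expect_equal(nf$zero_factors, 3L)
  after <- wonparafac:::cp_reconstruct(nf$G, nf$C, nf$D, scales = nf$scales)
  expect_equal(after, before, tolerance = 1e-10)
  # idempotent on an already-normalized model
  n2 <- normalize_and_sort(nf)
  expect_equal(n2$G, nf$G)
  expect_equal(n2$scales, nf$scales)
})

test_that("explained variation matches per-unit oracles and its edge cases", {
  f <- rand_factors(4, 3, 2, k = 2, seed = 71)
  rec <- wonparafac:::cp_reconstruct(f$G, f$C, f$D)
  fit <- won_parafac(rec, k = 2, w = 0, init = f, tol = 1e-12, max_iter = 2)
  expect_equal(explained_variation(fit, rec), 1, tolerance = 1e-9)
  # all-zero model -> 0
  z <- list(G = f$G * 0, C = f$C, D = f$D)
  a <- rand_cube(4, 3, 2, seed = 72)
  expect_equal(weighted_objective(a, NULL, z), sum(a^2))
  # random model vs triple-loop per-sample oracle
  ev <- explained_variation(fit, a, by = "sample")
  for (s in 1:3) {
    res2 <- tot2 <- 0
    for (ig in 1:4) for (id in 1:2) {
      r <- sum(fit$scales * fit$G[ig, ] * fit$C[s, ] * fit$D[id, ])
      res2 <- res2 + (r - a[ig, s, id])^2
      tot2 <- tot2 + a[ig, s, id]^2
    }
    expect_equal(unname(ev[s]), 1 - res2 / tot2, tolerance = 1e-9)
  }
  ev_l <- explained_variation(fit, a, by = "layer")
  expect_length(ev_l, 2)
  expect_true(all(ev_l <= 1))
})

test_that("data-type similarity is cosine between D rows with NA zero rows", {
  m <- list(D = rbind(c(1, 0), c(1, 1), c(1, 0), c(0, 0)))
  s <- dt_similarity(m)
  expect_equal(s[1, 2], 1 / sqrt(2))
  expect_equal(s[1, 3], 1)           # identical rows
  expect_equal(s[2, 2], 1)
  expect_true(all(is.na(s[4, ])))
  expect_equal(s, t(s))
  m2 <- list(D = rbind(c(1, 0), c(0, 1)))
  expect_equal(dt_similarity(m2)[1, 2], 0)  # disjoint support
})

test_that("with one layer and frozen D the fit reproduces multiplicative-update NMF", {
  set.seed(81)
  g <- 6; cc <- 5; k <- 2
  X <- matrix(runif(g * cc, 0.1, 1), g, cc)
  a <- array(X, dim = c(g, cc, 1))
  W0 <- matrix(runif(g * k, 0.1, 1), g, k)
  H0 <- matrix(runif(cc * k, 0.1, 1), cc, k)
  fit <- won_parafac(a, k = k, w = 0, weights = "unit",
                     init = list(G = W0, C = H0, D = matrix(1, 1, k)),
                     tol = 0, max_iter = 5,
                     update_modes = c("gene", "sample"), normalize = FALSE)
  # independent classical NMF oracle (Lee-Seung, X ~ W H^T), same init
  W <- W0; H <- H0
  for (i in 1:5) {
    W <- W * (X %*% H) / (W %*% crossprod(H))
    H <- H * (t(X) %*% W) / (H %*% crossprod(W))
  }
  expect_equal(fit$G, W, tolerance = 1e-10)
  expect_equal(fit$C, H, tolerance = 1e-10)
})

test_that("fit recovers planted factors and honours its reproducibility contract", {
  pl <- sim_planted_cube(sim_spec(g = 40, c = 30, d = 4, k_true = 3,
                                  noise_sd = 0, sparsity = 0.3, seed = 91))
  fit <- won_parafac(pl$cube, k = 3, w = 0, init = "eigen", tol = 1e-10,
                     max_iter = 1500, seed = 91)
  relerr <- sqrt(sum(residuals(fit)^2) / sum(pl$cube$values^2))
  expect_lt(relerr, 1e-3)
  expect_true(all(greedy_factor_cosine(coef(fit, "gene"), pl$truth$G) > 0.95))
  # bit-reproducible given (init, seed)
  fit2 <- won_parafac(pl$cube, k = 3, w = 0, init = "eigen", tol = 1e-10,
                      max_iter = 1500, seed = 91)
  expect_identical(fit$G, fit2$G)
  expect_identical(fit$objective_trace, fit2$objective_trace)
  # rank-1 cube: k = 1 recovers the factor triple up to scale at any w
  f1 <- rand_factors(10, 8, 3, k = 1, seed = 92)
  a1 <- wonparafac:::cp_reconstruct(f1$G, f1$C, f1$D)
  for (w in c(0, 0.5)) {
    r1 <- won_parafac(a1, k = 1, w = w, seed = 92, tol = 1e-12, max_iter = 500)
    expect_gt(abs(sum(r1$G[, 1] * f1$G[, 1])) /
                (sqrt(sum(r1$G^2)) * sqrt(sum(f1$G^2))), 0.999)
  }
  # non-negative cube contract
  neg <- array(-1, dim = c(2, 2, 2))
  expect_error(won_parafac(neg, k = 1), "non-negative")
})

test_that("model methods expose factors, fit and residuals coherently", {
  pl <- sim_planted_cube(sim_spec(g = 25, c = 18, d = 3, k_true = 2, seed = 101))
  fit <- won_parafac(pl$cube, k = 2, seed = 101, max_iter = 200)
  expect_s3_class(fit, "won_parafac")
  expect_identical(rownames(coef(fit, "sample")), pl$cube$sample_ids)
  expect_identical(dim(fitted(fit)), dim(pl$cube$values))
  expect_equal(fitted(fit) + residuals(fit), pl$cube$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_output(print(fit), "WON-PARAFAC")
  expect_output(print(summary(fit)), "explained variation")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$values >= 0))
  expect_identical(simulate(fit, seed = 5)[[1]]$values, sims[[1]]$values)
})
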