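# Projection of a new cohort onto frozen gene/data-type factors, permuted
# baselines, tissue linkage, Fisher separation and drug-response translation.

planted_small <- function(seed = 1, noise = 0) {
  sim_planted_cube(sim_spec(g = 40, c = 30, d = 4, k_true = 3,
                            noise_sd = noise, sparsity = 0.3, seed = seed))
}

test_that("projection recovers known cohort loadings under frozen G and D", {
  pl <- planted_small(seed = 11)
  fit <- model_from_truth(pl)
  coh <- sim_paired_cohort(pl, n_new = 25, seed = 12)
  pr <- project_cohort(fit, coh$cube, seed = 12, tol = 1e-10, max_iter = 800)
  expect_s3_class(pr, "cohort_projection")
  expect_true(all(pr$P >= 0))
  expect_true(all(greedy_factor_cosine(pr$P, coh$P_true) > 0.99))
  # objective never increases
  tr <- pr$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(head(tr, -1), 1e-12)))
  # all-zero sample fiber stays a zero row
  a0 <- coh$cube$values; a0[, 5, ] <- 0
  pr0 <- project_cohort(fit, a0, seed = 12, max_iter = 200)
  expect_equal(unname(pr0$P[5, ]), rep(0, 3))
  expect_output(print(pr), "cohort_projection")
})

test_that("projecting the training cube matches the joint fit's explained variation", {
  pl <- planted_small(seed = 21, noise = 0.05)
  fit <- won_parafac(pl$cube, k = 3, w = 0, init = "eigen", seed = 21,
                     tol = 1e-9, max_iter = 800)
  pr <- project_cohort(fit, pl$cube, seed = 21, tol = 1e-9, max_iter = 800)
  expect_lt(abs(pr$ev_total - explained_variation(fit)), 0.01)
})

test_that("axis mismatches are refused rather than silently subset", {
  pl <- planted_small(seed = 31)
  fit <- model_from_truth(pl)
  a <- pl$cube$values
  expect_error(project_cohort(fit, a[1:10, , ]), "axes")
  perm_names <- a; dimnames(perm_names)[[1]] <- rev(dimnames(a)[[1]])
  expect_error(project_cohort(fit, perm_names), "gene identifiers")
  relab <- a; dimnames(relab)[[3]] <- paste0("X", 1:4)
  expect_error(project_cohort(fit, relab), "layer names")
  # predict() dispatches to the projection
  pr <- predict(fit, pl$cube, seed = 31, max_iter = 50)
  expect_s3_class(pr, "cohort_projection")
})

test_that("structured cohorts beat their permuted baseline; noise cohorts do not", {
  pl <- planted_small(seed = 41, noise = 0.05)
  fit <- model_from_truth(pl)
  coh <- sim_paired_cohort(pl, n_new = 20, seed = 42)
  pr <- project_cohort(fit, coh$cube, seed = 42, max_iter = 300)
  pb <- permuted_baseline(fit, coh$cube, n_perm = 3, seed = 42, max_iter = 300)
  expect_identical(dim(pb), c(3L, 20L))
  expect_true(all(rowMeans(pb) < mean(pr$ev_sample)))
  # permutation is seed-reproducible
  pb2 <- permuted_baseline(fit, coh$cube, n_perm = 3, seed = 42, max_iter = 300)
  expect_identical(pb, pb2)
  # white-noise cohort: structured and permuted EV are indistinguishable
  set.seed(43)
  noise_cube <- array(runif(40 * 20 * 4), dim = c(40, 20, 4))
  prn <- project_cohort(fit, noise_cube, seed = 43, max_iter = 300)
  pbn <- permuted_baseline(fit, noise_cube, n_perm = 3, seed = 43, max_iter = 300)
  expect_lt(abs(mean(prn$ev_sample) - mean(pbn)), 0.05)
})

test_that("tissue association is the loading mass captured by a factor set", {
  P <- rbind(a = c(1, 1, 2), b = c(0, 0, 5), z = c(0, 0, 0))
  ta <- tissue_association(P, list(t3 = 3, all = 1:3))
  expect_equal(ta["a", "t3"], 0.5)
  expect_equal(ta["b", "t3"], 1)
  expect_equal(unname(ta[c("a", "b"), "all"]), c(1, 1))
  expect_true(all(is.na(ta["z", ])))
  # rows sum to 1 when the tissue sets partition the factors
  part <- tissue_association(P[1:2, ], list(x = 1:2, y = 3))
  expect_equal(unname(rowSums(part)), c(1, 1))
})

test_that("the Fisher criterion matches hand values and similarity invariance", {
  # 1-D example: groups {0,0,2,2} and {4,4,6,6} -> 16 / (1 + 1) = 8
  x <- c(0, 0, 2, 2, 4, 4, 6, 6)
  lab <- rep(c("a", "b"), each = 4)
  expect_equal(fisher_criterion(x, lab), 8)
  # identical distributions -> 0
  expect_equal(fisher_criterion(c(1, 2, 1, 2), rep(c("a", "b"), each = 2)), 0)
  # invariance under rotation, translation and scaling (2-D)
  set.seed(51)
  pts <- matrix(rnorm(40), 20, 2)
  lab2 <- rep(c("a", "b"), 10)
  f0 <- fisher_criterion(pts, lab2)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(fisher_criterion(pts %*% R, lab2), f0, tolerance = 1e-12)
  expect_equal(fisher_criterion(sweep(pts, 2, c(5, -3), "+"), lab2), f0,
               tolerance = 1e-12)
  expect_equal(fisher_criterion(pts * 4.2, lab2), f0, tolerance = 1e-12)
  # degenerate: distinct point masses -> +Inf with a warning
  expect_warning(v <- fisher_criterion(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
                 "zero within-group")
  expect_identical(v, Inf)
  expect_error(fisher_criterion(pts, rep("a", 20)), "two groups")
})

test_that("embedding separation contrasts feature spaces over repeated embeddings", {
  set.seed(61)
  n <- 30
  factor_feat <- matrix(runif(2 * n * 3), 2 * n, 3)   # cohorts share factor space
  raw_feat <- rbind(matrix(rnorm(n * 10), n, 10),
                    matrix(rnorm(n * 10, mean = 6), n, 10))  # raw-space batch shift
  cohort <- rep(c("cell", "pdx"), each = n)
  groups <- rep(rep(c("t1", "t2"), each = n / 2), 2)
  sep <- embedding_separation(list(raw = raw_feat, factor = factor_feat),
                              cohort, groups, n_repeats = 12, seed = 61)
  expect_setequal(unique(sep$space), c("raw", "factor"))
  expect_identical(nrow(sep), 12L * 2L * 2L)
  # factor-space criteria stochastically smaller than raw-space
  expect_lt(wilcox.test(sep$fisher[sep$space == "factor"],
                        sep$fisher[sep$space == "raw"],
                        alternative = "less")$p.value, 0.01)
  # single repeat with fixed seed reproduces exactly
  s1 <- embedding_separation(list(raw = raw_feat), cohort, groups,
                             n_repeats = 1, seed = 99)
  s2 <- embedding_separation(list(raw = raw_feat), cohort, groups,
                             n_repeats = 1, seed = 99)
  expect_identical(s1$fisher, s2$fisher)
  # a group absent from one cohort is skipped with a reason
  g2 <- groups; g2[cohort == "pdx" & g2 == "t2"] <- "t1"
  s3 <- embedding_separation(list(raw = raw_feat), cohort, g2,
                             n_repeats = 1, seed = 1)
  expect_identical(attr(s3, "skipped"), "t2")
  g3 <- c(rep("only_cell", n), rep("t1", n))   # no group spans both cohorts
  s4 <- embedding_separation(list(raw = raw_feat), cohort, g3,
                             n_repeats = 1, seed = 1)
  expect_identical(nrow(s4), 0L)
  expect_setequal(attr(s4, "skipped"), c("only_cell", "t1"))
})

test_that("drug models translate to cohort responses through projected loadings", {
  set.seed(71)
  n <- 100; k <- 4
  C <- matrix(runif(n * k), n, k, dimnames = list(paste0("s", 1:n), paste0("f", 1:k)))
  y <- setNames(drop(C %*% c(-2, 1, 0, 0)) + rnorm(n, sd = 0.1), rownames(C))
  m <- fit_drug_model(C, y, seed = 71, compound = "cmpdA")
  # cohort response simulated from the same linear factor model
  P <- matrix(runif(n * k), n, k, dimnames = list(paste0("px", 1:n), paste0("f", 1:k)))
  best_avg <- setNames(drop(P %*% c(-2, 1, 0, 0)) + rnorm(n, sd = 0.2), rownames(P))
  map <- data.frame(model_compound = "cmpdA", cohort_treatment = "trtA")
  tr <- translate_predictions(list(cmpdA = m), P, map,
                              cohort_response = cbind(trtA = best_avg))
  expect_identical(nrow(tr), 1L)
  expect_gt(tr$r, 0.5)
  expect_lt(tr$p, 1e-3)
  # shuffled response values decorrelate (names kept in place)
  shuf <- setNames(sample(unname(best_avg)), names(best_avg))
  tr0 <- translate_predictions(list(cmpdA = m), P, map,
                               cohort_response = cbind(trtA = shuf))
  expect_lt(abs(tr0$r), 0.3)
  # empty mapping warns and returns an empty table; unmapped compounds skipped
  expect_warning(e <- translate_predictions(list(cmpdA = m), P, map[0, ], best_avg),
                 "empty mapping")
  expect_identical(nrow(e), 0L)
  map2 <- rbind(map, data.frame(model_compound = "nope", cohort_treatment = "trtA"))
  tr2 <- translate_predictions(list(cmpdA = m), P, map2,
                               cohort_response = cbind(trtA = best_avg))
  expect_identical(nrow(tr2), 1L)
  expect_match(attr(tr2, "skipped"), "no fitted drug model")
})
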