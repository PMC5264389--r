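rand_problem <- function(seed, n = 20, p = 8, q = 3) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n, p)),
       Y = scale(matrix(rnorm(n * q), n, q)))
}

test_that("first component of a single-response fit is proportional to X'y", {
  pr <- rand_problem(71, q = 1)
  f <- fit_pls(pr$X, pr$Y, 1)
  w_ref <- as.vector(crossprod(pr$X, pr$Y))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  cosine <- abs(sum(f$weights[, 1] * w_ref))
  expect_equal(cosine, 1, tolerance = 1e-12)
})

test_that("a saturated model reproduces Y to machine precision", {
  set.seed(72)
  X <- scale(matrix(rnorm(25), 5, 5))
  Y <- scale(matrix(rnorm(15), 5, 3))
  f <- fit_pls(X, Y, 4)
  expect_lt(max(abs(f$fitted - Y)), 1e-10)
  expect_equal(unname(colSums(f$explained_y)), rep(100, 3), tolerance = 1e-9)
})

test_that("kernel fit agrees with an iterative NIPALS oracle up to signs", {
  for (seed in 73:77) {
    pr <- rand_problem(seed)
    f <- fit_pls(pr$X, pr$Y, 4)
    o <- nipals_pls2(pr$X, pr$Y, 4)
    expect_lt(max(abs(f$weights - align_signs(o$W, f$weights))), 1e-6)
    expect_lt(max(abs(f$scores - align_signs(o$TT, f$scores))), 1e-6)
    expect_lt(max(abs(f$x_loadings - align_signs(o$P, f$x_loadings))), 1e-6)
  }
})

test_that("fit invariants: unit weights, orthogonal scores, bounded variance", {
  pr <- rand_problem(78)
  f <- fit_pls(pr$X, pr$Y, 5)
  expect_equal(unname(colSums(f$weights^2)), rep(1, 5), tolerance = 1e-12)
  G <- crossprod(f$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_true(all(diff(cumsum(f$explained_x)) >= -1e-12))
  expect_lte(sum(f$explained_x), 100 + 1e-9)
  # regression coefficients reproduce the score-space fit
  expect_lt(max(abs(f$fitted - pr$X %*% f$coefficients[, , 5])), 1e-10)
  expect_error(fit_pls(pr$X, pr$Y, 25), "ncomp")
  expect_error(fit_pls(matrix(0, 5, 3), pr$Y[1:5, ], 2), "zero")
})

test_that("leave-one-out RMSEP matches the brute-force refit oracle", {
  set.seed(79)
  X <- matrix(rnorm(20), 5, 4)
  Y <- matrix(rnorm(10), 5, 2)
  expect_lt(max(abs(loo_rmsep(X, Y, 3) - loo_rmsep_brute(X, Y, 3))), 1e-12)
  expect_error(loo_rmsep(X, Y, 4), "ncomp_max")
})

test_that("RMSEP vanishes for an exact linear relation", {
  set.seed(80)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- X %*% matrix(c(1, -2, 0.5, 3, 1, 1, 0, -1), 4, 2)
  r <- loo_rmsep(X, Y, 4)
  expect_lt(max(r[4, ]), 1e-10)
})

test_that("pure-noise responses show the overfitting trend across seeds", {
  worse <- vapply(81:110, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 8), 12, 8)
    Y <- matrix(rnorm(12 * 2), 12, 2)
    r <- loo_rmsep(X, Y, 8)
    mean(r[8, ]) - mean(r[1, ])
  }, numeric(1))
  # overfitting: more components hurt prediction of noise, on average
  expect_gt(mean(worse > 0), 0.8)
  expect_gt(mean(worse), 0)
})

test_that("component selection takes per-response argmin and global max", {
  r <- matrix(c(3, 2, 2.5,
                4, 3.5, 3.6,
                5, 4, 4.5), nrow = 3,
              dimnames = list(NULL, c("lowhab", "midhab", "highhab")))
  sel <- select_components(r)
  expect_equal(unname(sel$per_response), c(2L, 2L, 2L))

  r2 <- matrix(1, 5, 3, dimnames = list(NULL, c("lowhab", "midhab", "highhab")))
  r2[4, 1] <- 0.5; r2[3, 2] <- 0.5; r2[3, 3] <- 0.5
  sel2 <- select_components(r2)
  expect_equal(unname(sel2$per_response), c(4L, 3L, 3L))
  expect_equal(sel2$global, 4L)

  # ties resolve to the smallest component count
  r3 <- matrix(c(2, 1, 1, 1), 4, 1)
  expect_equal(unname(select_components(r3)$per_response), 2L)
})

test_that("explained variance decomposition is conserved and interpretable", {
  # one dominant direction in X carries its share of variance on component 1
  set.seed(83)
  u <- rnorm(30)
  X <- cbind(u, u, u, u, matrix(rnorm(30 * 2, sd = 0.05), 30, 2))
  X <- scale(X)
  Y <- scale(matrix(u + rnorm(30, sd = 0.1), 30, 1))
  f <- fit_pls(X, Y, 3)
  ev <- explained_variance(f)
  expect_gt(ev$X[1], 60)
  # cumulative totals do not depend on how components are listed
  expect_equal(sum(ev$X), unname(ev$cumulative_X[3]))
  expect_equal(unname(colSums(ev$Y)), unname(ev$cumulative_Y[3, ]))
})

test_that("VIP: uniformity, normalization identity and brute-force oracle", {
  # one component with equal weights gives VIP = 1 everywhere
  set.seed(84)
  u <- rnorm(40)
  X <- scale(matrix(rep(u, 4), 40, 4) + matrix(rnorm(160, sd = 1e-6), 40, 4))
  Y <- scale(u + rnorm(40, sd = 0.1))
  f1 <- fit_pls(X, Y, 1)
  expect_equal(unname(vip(f1)), rep(1, 4), tolerance = 1e-3)

  for (seed in 85:89) {
    pr <- rand_problem(seed)
    f <- fit_pls(pr$X, pr$Y, 4)
    v <- vip(f)
    expect_equal(sum(v^2), f$p, tolerance = 1e-10)
    expect_equal(unname(v),
                 vip_brute(f$weights, f$scores, f$y_loadings),
                 tolerance = 1e-10)
  }

  pr <- rand_problem(90)
  f <- fit_pls(pr$X, pr$Y, 3)
  v_by_y <- vip(f, pooled = FALSE)
  expect_equal(dim(v_by_y), c(8L, 3L))
  expect_equal(unname(colSums(v_by_y^2)), rep(8, 3), tolerance = 1e-10)
})

test_that("interpretation thresholds, directions and sign invariance", {
  # a threshold above every |loading weight| flags no predictors
  set.seed(91)
  X <- scale(matrix(rnorm(30 * 20), 30, 20))
  Y <- scale(matrix(rowSums(X) + rnorm(30, sd = 0.5), 30, 1))
  colnames(Y) <- "lowhab"
  f <- fit_pls(X, Y, 2)
  rep1 <- interpret_pls(f, lw_threshold = max(abs(f$weights[, 1])) + 0.01,
                        ncomp = 1)
  expect_length(rep1$components[[1]]$predictors, 0L)
  # and the default threshold keeps only what exceeds it
  rep2 <- interpret_pls(f, ncomp = 1)
  expect_true(all(abs(rep2$components[[1]]$predictors) > 0.3))

  # a driver with negative effect on the decay rate reads as
  # "less habituation when the variable increases"
  rr <- recovery_result(seed = 92)
  expect_true(rr$signs)

  # flipping a component's joint signs leaves the determinants table intact
  rc <- recovery_cohort(93)
  nc <- normalize_intensity(rc$cohort$curves)
  cs <- label_centroids(kmeans_curves(nc, 3, n_restarts = 5, seed = 93))
  sp <- build_habituation_space(cityblock_to_centroids(nc, cs))
  X2 <- assemble_x(rc$descriptors, rc$cohort$ratings,
                   numeric_vars = paste0("D", 1:13), categorical_vars = "grp")
  Y2 <- assemble_y(sp, odorant_order = rownames(X2))
  f2 <- fit_pls(autoscale(X2), autoscale(Y2), 4)
  flipped <- f2
  for (a in c(2L, 4L)) {
    flipped$weights[, a] <- -flipped$weights[, a]
    flipped$x_loadings[, a] <- -flipped$x_loadings[, a]
    flipped$y_loadings[, a] <- -flipped$y_loadings[, a]
    flipped$scores[, a] <- -flipped$scores[, a]
  }
  expect_equal(interpret_pls(flipped)$determinants,
               interpret_pls(f2)$determinants)
  # predictions are unchanged by the joint flip
  expect_equal(flipped$scores %*% t(flipped$y_loadings),
               f2$scores %*% t(f2$y_loadings), tolerance = 1e-12)
})
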