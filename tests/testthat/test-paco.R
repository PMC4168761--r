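test_that("similarity transforms of a configuration superimpose exactly", {
  withr::with_seed(1, {
    X <- matrix(rnorm(16), 8, 2)
    theta <- runif(1, 0, 2 * pi)
  })
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 2.5 * X %*% R + matrix(c(10, -3), 8, 2, byrow = TRUE)
  fit <- procrustes_superimpose(X, Y)
  expect_lt(fit$m2, 1e-16)
  # mirrored copy: reflections are part of the admissible family
  Ym <- X %*% diag(c(-1, 1))
  expect_lt(procrustes_superimpose(X, Ym)$m2, 1e-16)
})

test_that("residuals sum to m2 and zero-width configurations are padded", {
  withr::with_seed(2, {
    X <- matrix(rnorm(12), 6, 2)
    Y <- matrix(rnorm(6), 6, 1)
  })
  fit <- procrustes_superimpose(X, Y)
  expect_equal(sum(fit$residuals), fit$m2, tolerance = 1e-9)
  expect_equal(length(fit$residuals), 6)
  expect_error(procrustes_superimpose(X[1, , drop = FALSE], Y[1, , drop = FALSE]),
               "at least 2")
  expect_error(procrustes_superimpose(X, Y[1:3, , drop = FALSE]), "equal row")
})

test_that("m2 matches grid-search minimisation on perturbed triangles", {
  # independent oracle: exhaustive search over rotation angle and
  # reflection, least-squares scale at each angle, centering for
  # translation
  grid_m2 <- function(X, Y) {
    Xc <- scale(X, scale = FALSE)
    Yc <- scale(Y, scale = FALSE)
    eval_angle <- function(theta, refl) {
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      if (refl) R <- R %*% diag(c(1, -1))
      Yr <- Yc %*% R
      s <- sum(Xc * Yr) / sum(Yr^2)
      sum((Xc - s * Yr)^2)
    }
    best <- Inf
    for (refl in c(FALSE, TRUE)) {
      coarse <- seq(0, 2 * pi, length.out = 2000)
      v <- vapply(coarse, eval_angle, numeric(1), refl = refl)
      i <- which.min(v)
      lo <- coarse[max(i - 1, 1)]; hi <- coarse[min(i + 1, length(coarse))]
      opt <- stats::optimize(eval_angle, c(lo, hi), refl = refl, tol = 1e-12)
      best <- min(best, opt$objective)
    }
    best
  }
  X <- rbind(c(0, 0), c(1, 0), c(0, 1))
  for (seed in 1:5) {
    Y <- X
    Y[2, ] <- Y[2, ] + withr::with_seed(seed, runif(2, -0.4, 0.4))
    fit <- procrustes_superimpose(X, Y)
    expect_equal(fit$m2, grid_m2(X, Y), tolerance = 1e-6)
  }
})

test_that("m2 agrees with the vegan procrustes reference", {
  skip_if_not_installed("vegan")
  withr::with_seed(9, {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
  })
  fit <- procrustes_superimpose(X, Y)
  ref <- vegan::procrustes(X, Y, symmetric = FALSE)
  expect_equal(fit$m2, ref$ss, tolerance = 1e-10)
})

test_that("perfect congruence gives m2 near zero and the minimal p", {
  D <- random_tree_dist(20, seed = 30)
  res <- paco_test(D, D, n_perm = 999, seed = 2)
  expect_lt(res$m2, 1e-16)
  expect_equal(res$p, 1 / 1000)
  expect_equal(sum(res$residuals), res$m2, tolerance = 1e-9)
  expect_identical(names(res$residuals), rownames(D))
})

test_that("m2 is invariant to joint relabeling and rigid motion", {
  D1 <- random_tree_dist(12, seed = 41)
  D2 <- random_tree_dist(12, seed = 42)
  r0 <- paco_test(D1, D2, n_perm = 9, seed = 1)
  perm <- withr::with_seed(3, sample(12))
  D1p <- as_distmat(unclass(D1)[perm, perm])
  D2p <- as_distmat(unclass(D2)[perm, perm])
  r1 <- paco_test(D1p, D2p, n_perm = 9, seed = 1)
  expect_equal(r1$m2, r0$m2, tolerance = 1e-9)
  # label-driven join: shuffling only one matrix's storage order changes nothing
  r2 <- paco_test(D1, D2p, n_perm = 9, seed = 1)
  expect_equal(r2$m2, r0$m2, tolerance = 1e-9)
})

test_that("mismatched labels and invalid permutation counts are refused", {
  D1 <- random_tree_dist(8, seed = 1)
  D2 <- unclass(random_tree_dist(8, seed = 2))
  rownames(D2)[1] <- colnames(D2)[1] <- "other"
  expect_error(paco_test(D1, as_distmat(D2)), "labels")
  expect_error(paco_test(D1, D1, n_perm = 0), "n_perm")
})

test_that("null permutation distribution equals an externally permuted pairing", {
  # permuting the fungal matrix before the test draws from the same null
  D1 <- random_tree_dist(15, seed = 55)
  D2 <- random_tree_dist(15, seed = 56)
  obs <- paco_test(D1, D2, n_perm = 299, seed = 8)
  pre <- withr::with_seed(99, sample(15))
  ids <- rownames(D2)
  D2p <- unclass(D2)[pre, pre]
  dimnames(D2p) <- list(ids, ids)
  shuffled <- paco_test(D1, as_distmat(D2p), n_perm = 299, seed = 8)
  ks <- suppressWarnings(stats::ks.test(obs$null_m2, shuffled$null_m2))
  expect_gt(ks$p.value, 0.001)
})

test_that("trait summaries of residuals behave on hand-built cases", {
  D <- random_tree_dist(6, seed = 3)
  res <- paco_test(D, D, n_perm = 9, seed = 1)
  # hand-set residuals: two groups {1,1} and {3,3}, two unlabelled 2s
  res$residuals[] <- c(1, 1, 3, 3, 2, 2)
  ids <- names(res$residuals)
  tr <- residuals_by_trait(res, stats::setNames(
    c("x", "x", "y", "y"), ids[1:4]))
  g <- tr$groups[order(tr$groups$trait), ]
  expect_equal(g$mean[g$trait == "x"], 1)
  expect_equal(g$mean[g$trait == "y"], 3)
  expect_equal(tr$overall_median, 2)

  # all-equal residuals: every group mean equals the overall median
  res$residuals[] <- rep(5, 6)
  tr2 <- residuals_by_trait(res, stats::setNames(c("u", "v"), ids[1:2]))
  expect_true(all(tr2$groups$mean == tr2$overall_median))

  # empty trait map: one unlabelled group with all specimens
  tr3 <- residuals_by_trait(res)
  expect_identical(tr3$groups$trait, "unlabelled")
  expect_equal(tr3$groups$n, 6L)

  expect_error(residuals_by_trait(res, c(zzz = "x")), "unknown")
})
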