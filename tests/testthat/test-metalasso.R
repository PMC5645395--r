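sim_datasets <- function(seed, M = 5, n = 40, P = 8, true = c(1, 3),
                         beta = c(2, -1.5), sd = 0.3) {
  set.seed(seed)
  lapply(seq_len(M), function(m) {
    x <- matrix(rnorm(n * P), n, P,
                dimnames = list(NULL, sprintf("r%02d", seq_len(P))))
    y <- as.numeric(x[, true, drop = FALSE] %*% beta + rnorm(n, 0, sd))
    list(y = y, x = x)
  })
}

test_that("hierarchical_subsets yields folds^rounds subsets of the right size", {
  part <- hierarchical_subsets(500, folds = 5, rounds = 2, seed = 1)
  expect_length(part$subsets, 25L)
  expect_true(all(lengths(part$subsets) == 320L))
  expect_true(all(vapply(part$subsets, function(s)
    all(s %in% 1:500) && !is.unsorted(s) && !anyDuplicated(s), logical(1))))
  # minimum feasible n
  part2 <- hierarchical_subsets(25, folds = 5, rounds = 2, seed = 1)
  expect_length(part2$subsets, 25L)
  expect_true(all(lengths(part2$subsets) == 16L))
  expect_error(hierarchical_subsets(24), "at least")
})

test_that("hierarchical_subsets is seed-deterministic and RNG-clean", {
  a <- hierarchical_subsets(60, seed = 7)
  set.seed(123); before <- .Random.seed
  b <- hierarchical_subsets(60, seed = 7)
  expect_identical(.Random.seed, before)  # RNG state restored
  expect_identical(a$subsets, b$subsets)
  c <- hierarchical_subsets(60, seed = 8)
  expect_false(identical(a$subsets, c$subsets))
})

test_that("fwl_residualize equals explicit projector and joint OLS", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 30
    X1 <- matrix(rnorm(n * 2), n, 2)
    X2 <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    Y <- rnorm(n)
    res <- fwl_residualize(Y, X1, X2)
    X1i <- cbind(1, X1)
    M <- diag(n) - X1i %*% solve(crossprod(X1i)) %*% t(X1i)
    expect_equal(res$Y, as.numeric(M %*% Y), tolerance = 1e-10)
    expect_equal(unname(res$X2), unname(M %*% X2), tolerance = 1e-10)
    # FWL theorem: regressing residualized Y on residualized X2 recovers
    # the X2 coefficients of the joint regression
    joint <- coef(lm(Y ~ X1 + X2))
    part <- coef(lm(res$Y ~ res$X2 - 1))
    expect_equal(unname(part), unname(joint[4:6]), tolerance = 1e-8)
  }
})

test_that("fwl_residualize handles rank-deficient backgrounds", {
  n <- 20
  X1 <- cbind(a = rnorm(n), b = 0)  # constant column, collinear with intercept
  X2 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "r"))
  Y <- rnorm(n)
  expect_silent(res <- fwl_residualize(Y, X1, X2))
  expect_equal(sum(res$Y * X1[, "a"]), 0, tolerance = 1e-8)
  expect_equal(sum(res$Y), 0, tolerance = 1e-8)
  expect_error(fwl_residualize(rnorm(2), matrix(rnorm(4), 2, 2),
                               matrix(rnorm(2), 2, 1)), "residualize")
})

test_that("soft_threshold shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0, 2), 0.5), c(-1.5, 0, 1.5))
})

test_that("fit_meta_lasso objective is monotone non-decreasing", {
  ds <- sim_datasets(11)
  f <- fit_meta_lasso(ds, w = 5, lambda = 2)
  expect_true(all(diff(f$objective) >= -1e-8))
  expect_true(f$converged)
})

test_that("fit_meta_lasso recovers planted supports and signs", {
  ds <- sim_datasets(12, n = 60)
  f <- fit_meta_lasso(ds, w = 10, lambda = 4)
  sel <- select_regulators(f)
  expect_setequal(sel$regulator_id, c("r01", "r03"))
  expect_equal(sel$sign[sel$regulator_id == "r01"], 1)
  expect_equal(sel$sign[sel$regulator_id == "r03"], -1)
  expect_true(all(sel$n_subsets_nonzero == length(ds)))
})

test_that("extreme penalties zero everything; zero response gives zero fit", {
  ds <- sim_datasets(13)
  f <- fit_meta_lasso(ds, w = 1e6, lambda = 1)
  expect_true(all(abs(f$g) < 1e-12))
  ds0 <- lapply(ds, function(d) { d$y <- rep(0, length(d$y)); d })
  f0 <- fit_meta_lasso(ds0, w = 1, lambda = 1)
  expect_true(all(abs(f0$g) < 1e-12))
  expect_true(all(abs(f0$zeta) < 1e-12))
})

test_that("zeta_fixed single-dataset fit matches the glmnet oracle", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 80; P <- 10
  x <- matrix(rnorm(n * P), n, P,
              dimnames = list(NULL, sprintf("r%02d", 1:P)))
  y <- as.numeric(x[, 2] * 1.5 - x[, 7] + rnorm(n, 0, 0.4))
  w <- 15
  f <- fit_meta_lasso(list(list(y = y, x = x)), w = w, lambda = 0,
                      zeta_fixed = TRUE)
  # same objective: glmnet minimizes (1/2n)RSS + lam*|b| on standardized x
  xs <- scale(x, center = TRUE, scale = apply(x, 2, function(v)
    sqrt(mean((v - mean(v))^2))))
  ys <- y - mean(y)
  g <- glmnet::glmnet(xs, ys, lambda = w / n, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(f$g), as.numeric(g$beta), tolerance = 1e-6)
})

test_that("RMS-1 zeta normalization holds for selected regulators", {
  ds <- sim_datasets(14, n = 60)
  f <- fit_meta_lasso(ds, w = 10, lambda = 4)
  for (p in which(abs(f$g) > 1e-8)) {
    z <- f$zeta[, p]
    expect_equal(sqrt(mean(z[z != 0]^2)), 1, tolerance = 1e-8)
  }
})

test_that("select_tuning picks the aggregate-BIC minimum, ties to larger", {
  ds <- sim_datasets(15, n = 60)
  tun <- select_tuning(ds, w_grid = c(2, 10, 1e6), lambda_grid = c(4, 1e6))
  expect_true(tun$w %in% c(2, 10, 1e6))
  expect_equal(nrow(tun$bic), 6L)
  expect_equal(min(tun$bic$bic),
               tun$bic$bic[tun$bic$w == tun$w & tun$bic$lambda == tun$lambda])
  sel <- select_regulators(tun$fit)
  expect_setequal(sel$regulator_id, c("r01", "r03"))
})

test_that("penalty scaling: units track the data scale; homogeneity law", {
  set.seed(31)
  n <- 100; P <- 6
  X2 <- matrix(rnorm(n * P), n, P,
               dimnames = list(NULL, sprintf("r%02d", 1:P)))
  y <- as.numeric(X2[, 1] * 2 + rnorm(n, 0, 0.5))
  m1 <- meta_lasso(y, X2 = X2, w = 0.2, lambda = 0.2, seed = 4)
  m2 <- meta_lasso(10 * y, X2 = X2, w = 0.2, lambda = 0.2, seed = 4)
  # scaled units: the effective penalties follow sd(y) exactly
  expect_equal(m2$tuning$w / m1$tuning$w, 10, tolerance = 1e-8)
  expect_equal(m2$penalty_scale[["lambda"]] / m1$penalty_scale[["lambda"]],
               10, tolerance = 1e-8)
  # exact homogeneity of the solver: y -> c y with w -> c w and
  # lambda -> c^2 lambda reproduces the solution with g scaled by c
  m3 <- meta_lasso(10 * y, X2 = X2,
                   w = m1$tuning$w * 10, lambda = m1$tuning$lambda * 100,
                   penalty_units = "absolute", seed = 4)
  expect_identical(m1$selection$regulator_id, m3$selection$regulator_id)
  nz <- abs(m1$fit$g) > 1e-8
  expect_equal(unname(m3$fit$g[nz] / m1$fit$g[nz]),
               rep(10, sum(nz)), tolerance = 1e-3)
})

test_that("meta_lasso methods: print, summary, coef, predict, residuals", {
  set.seed(32)
  n <- 60
  X2 <- matrix(rnorm(n * 4), n, 4,
               dimnames = list(NULL, c("tf_a", "mir_a", "mir_b", "mir_c")))
  y <- as.numeric(X2[, 1] * 2 + rnorm(n, 0, 0.3))
  fit <- meta_lasso(y, X2 = X2, seed = 9, gene_id = "g1",
                    condition = "ca:I")
  expect_s3_class(fit, "meta_lasso")
  expect_output(print(fit), "gene: *g1")
  expect_output(print(summary(fit)), "subsets")
  expect_length(coef(fit), 4L)
  expect_equal(dim(coef(fit, type = "dataset")), c(25L, 4L))
  pred <- predict(fit, X2)
  expect_length(pred, n)
  expect_gt(cor(pred, y), 0.8)
  expect_length(residuals(fit), 25L)
})

test_that("hierarchical_consistency votes across stages then cancers", {
  analysed <- data.frame(
    cancer_type = c("ca", "ca", "ca", "cb", "cb"),
    stage = c("I", "II", "III", "I", "II"))
  analysed$condition <- paste(analysed$cancer_type, analysed$stage,
                              sep = ":")
  sel <- data.frame(
    gene_id = "g1", regulator_id = "mirX",
    cancer_type = c("ca", "ca", "cb"),
    stage = c("I", "II", "I"),
    condition = c("ca:I", "ca:II", "cb:I"))
  cons <- hierarchical_consistency(sel, analysed, stage_fraction = 0.5,
                                   cancer_fraction = 0.5)
  # ca: 2 of 3 stages >= ceil(1.5); cb: 1 of 2 stages >= ceil(1) -> both in
  expect_setequal(cons$cancer_specific$cancer_type, c("ca", "cb"))
  # both of 2 cancers -> common
  expect_equal(nrow(cons$common), 1L)
  cons2 <- hierarchical_consistency(sel, analysed, stage_fraction = 0.9,
                                    cancer_fraction = 0.5)
  # ca needs 3 of 3 now, cb needs 2 of 2 -> neither qualifies
  expect_equal(nrow(cons2$cancer_specific), 0L)
  expect_equal(nrow(cons2$common), 0L)
})
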