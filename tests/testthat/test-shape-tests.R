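test_that("one-group MVT matches brute-force Hotelling T2", {
  set.seed(31)
  for (dims in list(c(12, 3), c(15, 4), c(10, 2))) {
    B <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    fit <- fit_mvm(B, intercept_design(dims[1]))
    res <- mvt_general(fit, hypothesis_spec(1, m = dims[2]))
    oracle <- oracle_hotelling_one_sample(B)
    expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
    expect_equal(res$df1, oracle$df1)
    expect_equal(res$df2, oracle$df2)   # n - m - q + 1 with q = 1
  }
})

test_that("MVT degenerations: univariate t^2, null data, two-sample T2", {
  set.seed(32)
  y <- rnorm(14)
  res <- mvt_general(fit_mvm(matrix(y), intercept_design(14)),
                     hypothesis_spec(1, m = 1))
  expect_equal(res$statistic, unname(t.test(y)$statistic^2), tolerance = 1e-10)

  B0 <- matrix(0, 8, 3)
  res0 <- mvt_general(fit_mvm(B0, intercept_design(8)), hypothesis_spec(1, m = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # identical columns: any zero-sum contrast gives F = 0 in both EXC forms
  Bi <- matrix(rnorm(8), 8, 3)
  fiti <- fit_mvm(Bi, intercept_design(8))
  expect_equal(xmv_interaction(fiti, hypothesis_spec(1, component_contrasts(3)))$statistic, 0)
  expect_equal(xuv_interaction(fiti, hypothesis_spec(1, component_contrasts(3)))$statistic, 0)

  # two-sample T2 against the textbook pooled-covariance formula
  n1 <- 10; n2 <- 12; m <- 3
  B1 <- matrix(rnorm(n1 * m), n1, m); B2 <- matrix(rnorm(n2 * m), n2, m) + 0.5
  d <- two_group_design(n1, n2)
  B <- rbind(B1, B2)
  fit <- fit_mvm(B, d$X)
  res2 <- mvt_general(fit, hypothesis_spec(c(0, 1), m = m))
  Sp <- ((n1 - 1) * cov(B1) + (n2 - 1) * cov(B2)) / (n1 + n2 - 2)
  dlt <- colMeans(B1) - colMeans(B2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(dlt) %*% solve(Sp) %*% dlt)
  f_oracle <- T2 * (n1 + n2 - m - 1) / ((n1 + n2 - 2) * m)
  expect_equal(res2$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res2$df2, n1 + n2 - m - 2 + 1)
})

test_that("MVT whole-profile test is invariant to invertible recombination of components; reductions are not", {
  set.seed(33)
  B <- matrix(rnorm(20 * 4), 20, 4)
  X <- intercept_design(20)
  Tm <- matrix(rnorm(16), 4, 4)
  while (abs(det(Tm)) < 0.1) Tm <- matrix(rnorm(16), 4, 4)
  f1 <- mvt_general(fit_mvm(B, X), hypothesis_spec(1, m = 4))
  f2 <- mvt_general(fit_mvm(B %*% Tm, X), hypothesis_spec(1, m = 4))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-8)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)

  a1 <- reduced_test(reduce_components(B), X)
  a2 <- reduced_test(reduce_components(B %*% Tm), X)
  expect_gt(abs(a1$statistic - a2$statistic), 1e-6)
})

test_that("XUV equals the explicit long-format repeated-measures ANOVA", {
  set.seed(34)
  for (dims in list(c(10, 4), c(12, 7), c(8, 3))) {
    B <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    fit <- fit_mvm(B, intercept_design(dims[1]))
    res <- xuv_interaction(fit, hypothesis_spec(1, component_contrasts(dims[2])),
                           correction = "none")
    expect_equal(res$statistic, oracle_rm_anova_f(B), tolerance = 1e-10)
    expect_equal(res$df1, dims[2] - 1)
    expect_equal(res$df2, (dims[2] - 1) * (dims[1] - 1))
  }
})

test_that("XUV two-component case degenerates to the squared paired t", {
  set.seed(35)
  B <- matrix(rnorm(18), 9, 2)
  fit <- fit_mvm(B, intercept_design(9))
  hyp <- hypothesis_spec(1, component_contrasts(2))
  t2 <- unname(t.test(B[, 1], B[, 2], paired = TRUE)$statistic^2)
  expect_equal(xuv_interaction(fit, hyp, "none")$statistic, t2, tolerance = 1e-10)
  # with a single contrast XMV coincides as well
  expect_equal(xmv_interaction(fit, hyp)$statistic, t2, tolerance = 1e-10)
})

test_that("XUV/XMV results do not depend on the zero-sum contrast basis", {
  set.seed(36)
  B <- matrix(rnorm(14 * 5), 14, 5)
  fit <- fit_mvm(B, intercept_design(14))
  M1 <- component_contrasts(5)
  # successive-difference contrasts: same span, different basis
  M2 <- matrix(0, 5, 4)
  for (j in 1:4) { M2[j, j] <- 1; M2[j + 1, j] <- -1 }
  r1 <- xuv_interaction(fit, hypothesis_spec(1, M1), "GG")
  r2 <- xuv_interaction(fit, hypothesis_spec(1, M2), "GG")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-8)
  expect_equal(r1$epsilon, r2$epsilon, tolerance = 1e-8)
  m1 <- xmv_interaction(fit, hypothesis_spec(1, M1))
  m2 <- xmv_interaction(fit, hypothesis_spec(1, M2))
  expect_equal(m1$statistic, m2$statistic, tolerance = 1e-8)
})

test_that("sphericity: compound-symmetric contrast covariance gives epsilon 1; corrections scale both DFs", {
  # construct data whose contrast covariance is exactly spherical
  set.seed(37)
  n <- 40; m <- 4
  Z <- matrix(rnorm(n * m), n, m)
  # whiten then color with a compound-symmetric covariance
  Z <- Z %*% solve(chol(cov(Z)))
  Sig_cs <- 0.5 * diag(m) + 0.5
  B <- Z %*% chol(Sig_cs)
  fit <- fit_mvm(B, intercept_design(n))
  res <- xuv_interaction(fit, hypothesis_spec(1, component_contrasts(m)), "GG")
  expect_equal(res$epsilon, 1, tolerance = 1e-8)
  expect_equal(res$df1, m - 1, tolerance = 1e-6)

  # AR(1)-like data: epsilon < 1 and DFs shrink proportionally
  B2 <- random_effect_matrix(20, 6, seed = 38)
  fit2 <- fit_mvm(B2, intercept_design(20))
  gg <- xuv_interaction(fit2, hypothesis_spec(1, component_contrasts(6)), "GG")
  none <- xuv_interaction(fit2, hypothesis_spec(1, component_contrasts(6)), "none")
  expect_lt(gg$epsilon, 1)
  expect_gte(gg$epsilon, 1 / 5)
  expect_equal(gg$df1 / none$df1, gg$epsilon, tolerance = 1e-10)
  expect_equal(gg$df2 / none$df2, gg$epsilon, tolerance = 1e-10)
  expect_equal(gg$statistic, none$statistic)  # epsilon moves DFs, not F
})

test_that("XMV matches brute-force Hotelling on difference scores", {
  set.seed(39)
  B <- matrix(rnorm(15 * 4), 15, 4)
  fit <- fit_mvm(B, intercept_design(15))
  res <- xmv_interaction(fit, hypothesis_spec(1, component_contrasts(4)))
  D <- B[, 1:3] - B[, 2:4]    # difference scores span the contrast space
  oracle <- oracle_hotelling_one_sample(D)
  expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(3, 15 - 3 - 1 + 1))
})

test_that("XMV infeasible when contrasts outnumber error DF", {
  B <- random_effect_matrix(6, 7, seed = 40)
  fit <- fit_mvm(B, intercept_design(6))
  expect_error(xmv_interaction(fit, hypothesis_spec(1, component_contrasts(7))),
               "infeasible")
})

test_that("XUV F is ~0 for perfectly parallel profiles while MVT/AUC reject a flat nonzero profile", {
  # flat nonzero one-group data: on the null line of the interaction test
  set.seed(41)
  n <- 25; m <- 5
  level <- 3 + rnorm(n, sd = 0.2)       # per-subject flat profile
  B <- matrix(level, n, m) + matrix(rnorm(n * m, sd = 1e-3), n, m)
  fit <- fit_mvm(B, intercept_design(n))
  xuv <- xuv_interaction(fit, hypothesis_spec(1, component_contrasts(m)), "none")
  mvt <- mvt_general(fit, hypothesis_spec(1, m = m))
  auc <- reduced_test(reduce_components(B), intercept_design(n))
  expect_gt(xuv$p, 0.01)      # no shape effect to find
  expect_lt(mvt$p, 1e-6)
  expect_lt(auc$p, 1e-6)
})

test_that("reductions compute sums, norms, and signed norms", {
  B <- rbind(c(1, 2, -1), c(0, 0, 0), c(-3, 4, 0))
  expect_equal(reduce_components(B), c(2, 0, 1))
  expect_equal(reduce_components(B, "l2d"), c(sqrt(6), 0, 5))
  expect_true(all(reduce_components(B, "l2d") >= 0))
  expect_equal(reduce_components(rbind(c(-3, 4)), "l2d", signed = TRUE,
                                 sign_component = 1), -5)
  expect_error(reduce_components(B, weights = c(0, 0, 0)), "not all be zero")
})

test_that("reduced_test equals the squared t test in one- and two-sample forms", {
  set.seed(42)
  v <- rnorm(30)
  r1 <- reduced_test(v, intercept_design(30))
  expect_equal(r1$statistic, unname(t.test(v)$statistic^2), tolerance = 1e-10)
  expect_equal(c(r1$df1, r1$df2), c(1, 29))

  d <- two_group_design(12, 14)
  v2 <- rnorm(26)
  r2 <- reduced_test(v2, d$X, c(0, 1), method = "AUC")
  tt <- t.test(v2[1:12], v2[13:26], var.equal = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(r2$df2, 24)

  # identical groups give F = 0
  v3 <- rep(c(1, 2, 3), 4)
  d3 <- two_group_design(6, 6)
  expect_equal(reduced_test(c(v3[1:6], v3[1:6]), d3$X, c(0, 1))$statistic, 0,
               tolerance = 1e-20)
})

test_that("f_to_z maps the F median to 0, preserves p, and stays finite for tiny p", {
  expect_equal(f_to_z(qf(0.5, 3, 17), 3, 17), 0, tolerance = 1e-10)
  expect_equal(f_to_z(qf(0.95, 5, 40), 5, 40), qnorm(0.95), tolerance = 1e-8)
  # equal p, different DFs -> same z
  z1 <- f_to_z(qf(0.9, 2, 10), 2, 10)
  z2 <- f_to_z(qf(0.9, 7, 100), 7, 100)
  expect_equal(z1, z2, tolerance = 1e-8)
  # far tail stays finite via the log-scale path
  expect_true(is.finite(f_to_z(1e6, 7, 200)))
  expect_gt(f_to_z(1e6, 7, 200), 8)
  expect_error(f_to_z(1, -1, 10), "positive")
})

test_that("all tests are invariant to permutation of subject rows", {
  set.seed(43)
  B <- matrix(rnorm(16 * 4), 16, 4)
  perm <- sample(16)
  X <- intercept_design(16)
  for (meth in c("MVT", "XUV", "XMV", "AUC", "L2D")) {
    r1 <- run_shape_tests(B, X, methods = meth)
    r2 <- run_shape_tests(B[perm, ], X, methods = meth)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  }
})

test_that("equal-AUC groups with different shapes: AUC blind, XUV/MVT see the difference", {
  # two mean curves with identical sums but different shapes
  mu1 <- c(0, 1, 2, 1, 0)
  mu2 <- c(1.2, 0.4, 0.8, 0.4, 1.2)   # same sum = 4
  expect_equal(sum(mu1), sum(mu2))
  set.seed(44)
  reps <- 300; n <- 20
  rej <- c(AUC = 0, XUV = 0, MVT = 0)
  d <- two_group_design(n, n)
  for (r in seq_len(reps)) {
    B <- rbind(matrix(rnorm(n * 5, sd = 0.6), n, 5) + rep(mu1, each = n),
               matrix(rnorm(n * 5, sd = 0.6), n, 5) + rep(mu2, each = n))
    res <- run_shape_tests(B, d$X, effect = "Group",
                           methods = c("AUC", "XUV", "MVT"))
    rej <- rej + (setNames(res$p, res$method)[names(rej)] < 0.05)
  }
  prop <- rej / reps
  expect_lt(prop["AUC"], 0.12)   # near the nominal level
  expect_gt(prop["XUV"], 0.9)
  expect_gt(prop["MVT"], 0.9)
})
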