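test_that("intercept-only and effect-coded designs are built as declared", {
  st1 <- data.frame(Subj = c("a", "b", "c"))
  X1 <- encode_between_design(design_spec(), st1)
  expect_equal(unname(X1[, 1]), c(1, 1, 1))
  expect_equal(ncol(X1), 1L)

  d <- two_group_design(2, 2)
  expect_equal(unname(d$X[, 2]), c(1, 1, -1, -1))
  expect_equal(ncol(d$X), 2L)

  # treatment coding as the alternative
  spt <- design_spec(between_factors = list(Group = c("g1", "g2")),
                     coding = "treatment")
  Xt <- encode_between_design(spt, d$subject_table)
  expect_equal(unname(Xt[, 2]), c(0, 0, 1, 1))
})

test_that("within-group centered covariate with group:age interaction gives q = 4", {
  set.seed(11)
  st <- data.frame(Subj = paste0("s", 1:50),
                   Group = rep(c("child", "adult"), c(21, 29)),
                   age = c(rnorm(21, 10, 2), rnorm(29, 30, 5)))
  sp <- design_spec(between_factors = list(Group = c("child", "adult")),
                    covariates = list(age = "within"),
                    interactions = list(c("Group", "age")))
  X <- encode_between_design(sp, st)
  expect_equal(ncol(X), 4L)
  expect_equal(sum(X[st$Group == "child", "age"]), 0)
  expect_equal(sum(X[st$Group == "adult", "age"]), 0)
  tc <- attr(X, "term_cols")
  expect_named(tc, c("(Intercept)", "Group", "age", "Group:age"))
})

test_that("design errors: aliased columns are named, unknown levels refused", {
  st <- data.frame(Subj = c("a", "b", "c", "d"),
                   Group = c("g1", "g1", "g2", "g2"),
                   dup = c(1, 1, -1, -1))
  sp <- design_spec(between_factors = list(Group = c("g1", "g2")),
                    covariates = list(dup = "none"))
  expect_error(encode_between_design(sp, st), "aliased.*dup")

  sp2 <- design_spec(between_factors = list(Group = c("g1", "g2")))
  st2 <- data.frame(Subj = c("a", "b"), Group = c("g1", "g3"))
  expect_error(encode_between_design(sp2, st2), "unknown level")
})

test_that("within-subject factors flatten row-major over the declared order", {
  sp <- design_spec(within_factors = list(Cond = c("con", "inc"), Component = 3))
  expect_equal(within_cell_labels(sp),
               c("Cond.con_Component1", "Cond.con_Component2", "Cond.con_Component3",
                 "Cond.inc_Component1", "Cond.inc_Component2", "Cond.inc_Component3"))
})

test_that("fit_mvm solves the normal equations column by column", {
  set.seed(21)
  B <- matrix(rnorm(24), 8, 3)
  X <- cbind(1, rnorm(8))
  fit <- fit_mvm(B, X)
  # brute-force per-column ordinary least squares
  for (j in 1:3) {
    bj <- solve(t(X) %*% X, t(X) %*% B[, j])
    expect_equal(unname(fit$coef[, j]), drop(bj), tolerance = 1e-12)
  }
  R <- B - X %*% fit$coef
  expect_equal(fit$residual_ssp, t(R) %*% R,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fit$dims, c(n = 8L, m = 3L, q = 2L))
})

test_that("fit_mvm degenerate cases: intercept gives means, exact fit gives zero SSP", {
  set.seed(22)
  B <- matrix(rnorm(30), 10, 3)
  fit <- fit_mvm(B, intercept_design(10))
  expect_equal(drop(fit$coef), colMeans(B), ignore_attr = TRUE)

  X <- cbind(1, rep(c(0, 1), 5))
  A0 <- matrix(c(1, 2, 3, -1, 0.5, 2), 2, 3)
  fitp <- fit_mvm(X %*% A0, X)
  expect_equal(unname(fitp$coef), A0, tolerance = 1e-10)
  expect_equal(max(abs(fitp$residual_ssp)), 0, tolerance = 1e-18)

  expect_error(fit_mvm(matrix(rnorm(6), 2, 3), cbind(1, c(0, 1))),
               "insufficient subjects")
  expect_error(fit_mvm(B, cbind(1, rep(2, 10))), "rank deficient")
})

test_that("residual SSP is invariant to reparameterization and non-increasing in nesting", {
  set.seed(23)
  for (rep in 1:5) {
    B <- matrix(rnorm(15 * 4), 15, 4)
    X <- cbind(1, rnorm(15), rnorm(15))
    T_inv <- matrix(rnorm(9), 3, 3)
    while (abs(det(T_inv)) < 0.1) T_inv <- matrix(rnorm(9), 3, 3)
    E1 <- fit_mvm(B, X)$residual_ssp
    E2 <- fit_mvm(B, X %*% T_inv)$residual_ssp
    expect_equal(E1, E2, tolerance = 1e-8, ignore_attr = TRUE)
    # adding a column cannot increase the residual trace
    E3 <- fit_mvm(B, cbind(X, rnorm(15)))$residual_ssp
    expect_lte(sum(diag(E3)), sum(diag(E1)) + 1e-10)
  }
})

test_that("effect_matrix validates its invariants", {
  expect_error(effect_matrix(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
  expect_error(effect_matrix(matrix(1:4, 2, 2), subject_ids = c("a", "a")),
               "unique")
  expect_error(effect_matrix(matrix(1:3, 1, 3)), "2 subjects")
})
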