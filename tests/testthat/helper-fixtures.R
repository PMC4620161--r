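# shared fixture builders for the test suite

random_effect_matrix <- function(n, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  effect_matrix(matrix(rnorm(n * m), n, m))
}

# two-group stacked design: n1 + n2 subjects, effect-coded group column
two_group_design <- function(n1, n2) {
  st <- data.frame(Subj = paste0("s", seq_len(n1 + n2)),
                   Group = rep(c("g1", "g2"), c(n1, n2)))
  sp <- design_spec(between_factors = list(Group = c("g1", "g2")))
  list(X = encode_between_design(sp, st), subject_table = st, spec = sp)
}

intercept_design <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

# brute-force one-sample Hotelling T2 as an F statistic, independent of the
# package's fitting path
oracle_hotelling_one_sample <- function(B) {
  n <- nrow(B); m <- ncol(B)
  xbar <- colMeans(B)
  S <- stats::cov(B)
  T2 <- n * drop(t(xbar) %*% solve(S) %*% xbar)
  list(f = T2 * (n - m) / (m * (n - 1)), df1 = m, df2 = n - m)
}

# builds a tiny synthetic 4 x 4 x 2 image set from a scenario: every voxel
# carries an independent draw of the same group design, one 4D file per
# subject (m volumes)
make_voxelwise_fixture <- function(dir, n_per_group = 8, seed = 71) {
  sc <- make_scenario("2a")
  grid <- c(4L, 4L, 2L)
  nvox <- prod(grid)
  m <- sc$m
  groups <- rep(c("g1", "g2"), each = n_per_group)
  n <- length(groups)
  data <- array(0, c(n, m, nvox))
  for (v in seq_len(nvox)) {
    d <- simulate_betas(sc, n_per_group, seed = as.integer(seed + 7919 * v))
    data[, , v] <- rbind(unclass(d[[1]]), unclass(d[[2]]))
  }
  manifest <- NULL
  for (i in seq_len(n)) {
    img <- array(0, c(grid, m))
    for (j in seq_len(m)) img[, , , j] <- array(data[i, j, ], grid)
    f <- file.path(dir, sprintf("subj%02d.nii.gz", i))
    RNifti::writeNifti(RNifti::asNifti(img), f)
    manifest <- rbind(manifest,
                      data.frame(Subj = sprintf("s%02d", i), Group = groups[i],
                                 Cell = paste0("t", seq_len(m)), File = f,
                                 Volume = seq_len(m)))
  }
  list(manifest = manifest, data = data, grid = grid, groups = groups)
}

# explicit long-format repeated-measures ANOVA (subject as error stratum)
# for the one-group component main effect
oracle_rm_anova_f <- function(B) {
  n <- nrow(B); m <- ncol(B)
  long <- data.frame(y = as.vector(B),
                     s = factor(rep(seq_len(n), m)),
                     comp = factor(rep(seq_len(m), each = n)))
  grand <- mean(long$y)
  ss_comp <- n * sum((tapply(long$y, long$comp, mean) - grand)^2)
  ss_subj <- m * sum((tapply(long$y, long$s, mean) - grand)^2)
  ss_tot <- sum((long$y - grand)^2)
  ss_err <- ss_tot - ss_comp - ss_subj
  df_comp <- m - 1
  df_err <- (m - 1) * (n - 1)
  (ss_comp / df_comp) / (ss_err / df_err)
}
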