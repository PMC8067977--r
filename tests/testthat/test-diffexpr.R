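test_that("consensus correlation tracks the intraclass correlation", {
  ann <- make_annotation(8)
  des <- design_spec(ann)
  n <- nrow(ann)

  # subject SD 1, residual SD 0.1: true ICC ~ 0.99
  set.seed(1)
  subj_eff <- matrix(rnorm(200 * 8), 200, 8)
  X_hi <- subj_eff[, match(ann$subject_id, unique(ann$subject_id))] +
    matrix(rnorm(200 * n, 0, 0.1), 200, n)
  colnames(X_hi) <- ann$sample_id
  expect_gt(estimate_consensus_correlation(X_hi, des), 0.9)

  # no subject effect: consensus near 0
  set.seed(2)
  X_null <- matrix(rnorm(1000 * n), 1000, n,
                   dimnames = list(NULL, ann$sample_id))
  expect_lt(abs(estimate_consensus_correlation(X_null, des)), 0.05)
})

test_that("all-singleton blocks give consensus 0 with a warning", {
  ann <- make_annotation(4)
  ann <- ann[!duplicated(ann$subject_id), ]
  des <- design_spec(ann)
  X <- matrix(rnorm(20 * nrow(ann)), 20, nrow(ann),
              dimnames = list(NULL, ann$sample_id))
  expect_warning(rho <- estimate_consensus_correlation(X, des), "singleton")
  expect_equal(rho, 0)
})

test_that("GLS group-means fit matches the closed-form oracle", {
  ann <- make_annotation(5)
  des <- design_spec(ann)
  n <- nrow(ann)

  # rho = 0 reduces to per-group means
  set.seed(3)
  X <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(sprintf("g%02d", 1:30), ann$sample_id))
  fit0 <- fit_group_means(X, des, rho = 0)
  means <- t(apply(X, 1, function(y) tapply(y, des$group, mean)))
  expect_equal(unname(fit0$coefficients), unname(means[, des$levels]),
               tolerance = 1e-12)

  # noiseless planted means recovered exactly
  mu <- c(NECneg = 1, NECpos = 2, TECneg = 3, TECpos = 4)
  Xp <- matrix(rep(mu[as.character(des$group)], each = 2), 2, n,
               dimnames = list(c("a", "b"), ann$sample_id))
  fitp <- fit_group_means(Xp, des, rho = 0.3)
  expect_equal(unname(fitp$coefficients[1, ]), unname(mu), tolerance = 1e-10)

  # explicit (X' V^-1 X)^-1 X' V^-1 y oracle at rho = 0.5, 20 fixtures
  rho <- 0.5
  V <- diag(n)
  for (idx in split(seq_len(n), des$block)) V[idx, idx] <- rho
  diag(V) <- 1
  Vi <- solve(V)
  D <- des$design
  H <- solve(t(D) %*% Vi %*% D) %*% t(D) %*% Vi
  for (s in 1:20) {
    set.seed(s)
    y <- rnorm(n)
    Y <- matrix(y, 1, n, dimnames = list("g", ann$sample_id))
    fit <- fit_group_means(Y, des, rho = rho)
    expect_equal(as.numeric(fit$coefficients), as.numeric(H %*% y),
                 tolerance = 1e-10)
    r <- y - as.numeric(D %*% t(fit$coefficients))
    expect_equal(fit$sigma2[["g"]],
                 as.numeric(t(r) %*% Vi %*% r) / (n - 4), tolerance = 1e-10)
  }
})

test_that("moderated t has the expected shrinkage limits", {
  ann <- make_annotation(6)
  des <- design_spec(ann)
  n <- nrow(ann)

  # < 10 genes: fallback to d0 = 0, i.e. ordinary t
  set.seed(4)
  X <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), ann$sample_id))
  fit <- fit_group_means(X, des, rho = 0)
  expect_warning(tab <- moderate_and_test(fit, "TECneg_vs_NECneg"), "fewer")
  cv <- des$contrasts$TECneg_vs_NECneg
  se <- sqrt(as.numeric(t(cv) %*% fit$cov_unscaled %*% cv) * fit$sigma2)
  expect_equal(unname(tab$t), unname(as.numeric(fit$coefficients %*% cv) / se),
               tolerance = 1e-12)
  expect_equal(attr(tab, "df_prior"), 0)

  # identical residual variances: complete shrinkage, s2_post = s0^2 for
  # every gene, so every moderated t coincides
  Xeq <- X[rep(1, 20), ]
  rownames(Xeq) <- paste0("h", 1:20)
  fiteq <- fit_group_means(Xeq, des, rho = 0)
  tabeq <- moderate_and_test(fiteq, "TECneg_vs_NECneg")
  expect_equal(attr(tabeq, "df_prior"), Inf)
  expect_lt(diff(range(tabeq$t)), 1e-10)
  # the prior variance is the chi-square-bias-corrected common variance
  df <- fiteq$df_residual
  expect_equal(attr(tabeq, "var_prior"),
               fiteq$sigma2[[1]] * exp(log(df / 2) - digamma(df / 2)),
               tolerance = 1e-10)
})

test_that("moderated t is monotone in |log2FC| at fixed variance", {
  ann <- make_annotation(6)
  des <- design_spec(ann)
  n <- nrow(ann)
  set.seed(5)
  base <- rnorm(n)
  shifts <- seq(0, 3, length.out = 12)
  X <- t(sapply(shifts, function(s) {
    base + s * as.numeric(des$group == "TECneg")
  }))
  rownames(X) <- sprintf("g%02d", seq_along(shifts))
  colnames(X) <- ann$sample_id
  fit <- fit_group_means(X, des, rho = 0)
  tab <- moderate_and_test(fit, "TECneg_vs_NECneg")
  ord <- order(abs(tab$log2FC))
  expect_true(all(diff(abs(tab$t[ord])) >= -1e-12))
})

test_that("BH adjustment matches the step-up oracle and the hand example", {
  p <- c(0.01, 0.04, 0.03, 0.02)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(bh_oracle(p), rep(0.04, 4))
  for (s in 1:20) {
    set.seed(s)
    pr <- runif(30)^2
    expect_equal(p.adjust(pr, "BH"), bh_oracle(pr), tolerance = 1e-12)
  }
  # monotone non-decreasing in raw-p order, bounded by 1
  set.seed(99)
  pr <- runif(50)
  adj <- p.adjust(pr, "BH")
  expect_true(all(diff(adj[order(pr)]) >= -1e-15))
  expect_true(all(adj <= 1))
})

test_that("the moderated pipeline agrees with limma on blocked data", {
  skip_if_not_installed("limma")
  cfg <- sim_config(seed = 31, n_modules = 2, module_sizes = c(40, 40),
                    origin_effects = c(2, 0), activation_effects = c(0, 1.5),
                    n_background_genes = 300, background_low_mean = 7,
                    n_outlier_samples = 0, subject_sd = 0.5)
  ann <- simulate_cohort(cfg)
  X <- simulate_expression(cfg, ann)$expr
  des <- design_spec(ann)
  rho <- estimate_consensus_correlation(X, des)
  dc <- limma::duplicateCorrelation(X, des$design, block = des$block)
  expect_equal(rho, dc$consensus.correlation, tolerance = 0.1)
  fit <- fit_group_means(X, des, rho = rho)
  tab <- moderate_and_test(fit, "TECneg_vs_NECneg")
  lf <- limma::lmFit(X, des$design, block = des$block,
                     correlation = dc$consensus.correlation)
  cm <- limma::makeContrasts(TECneg - NECneg, levels = des$design)
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))
  expect_gt(cor(tab$t, eb$t[, 1]), 0.999)
  expect_lt(max(abs(tab$log2FC - eb$coefficients[, 1])), 0.05)
})
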