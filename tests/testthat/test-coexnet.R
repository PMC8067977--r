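test_that("bicor has correlation limits and matches the weight formula", {
  x <- rnorm(20)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  expect_error(bicor(x, x[-1]), "length")

  # gross outlier: robust to it, and equal to a direct implementation
  x <- 1:20
  y <- x
  y[20] <- 100
  direct_bicor <- function(a, b) {
    norm1 <- function(v) {
      u <- (v - median(v)) / (9 * median(abs(v - median(v))))
      w <- (1 - u^2)^2 * (abs(u) < 1)
      a0 <- (v - median(v)) * w
      a0 / sqrt(sum(a0^2))
    }
    sum(norm1(a) * norm1(b))
  }
  expect_equal(bicor(x, y), direct_bicor(x, y), tolerance = 1e-12)
  expect_gt(bicor(x, y), cor(x, y))

  # MAD = 0 vectors fall back to Pearson
  z1 <- c(rep(0, 15), 1:5)
  z2 <- c(rep(2, 15), 5:1)
  expect_equal(bicor(z1, z2), cor(z1, z2), tolerance = 1e-12)
  expect_true(abs(bicor(z1, rnorm(20))) <= 1)  # mixed fallback stays bounded
})

test_that("bicor_matrix equals pairwise bicor and stays in [-1, 1]", {
  set.seed(1)
  X <- matrix(rnorm(8 * 15), 8, 15)
  C <- bicor_matrix(X)
  expect_true(isSymmetric(C, tol = 1e-12))
  expect_true(all(abs(C) <= 1))
  for (i in 1:4) for (j in 5:8) {
    expect_equal(C[i, j], bicor(X[i, ], X[j, ]), tolerance = 1e-12)
  }
})

test_that("signed adjacency has the closed-form values at c in {-1, 0, 1}", {
  C <- matrix(c(1, -1, 0, -1, 1, 1, 0, 1, 1), 3, 3)
  A <- signed_adjacency(C, beta = 12)
  expect_equal(A[1, 2], 0)
  expect_equal(A[1, 3], 0.5^12)
  expect_equal(A[2, 3], 1)
  expect_equal(diag(A), rep(1, 3))
})

test_that("TOM matches the hand example and a triple-loop oracle", {
  A <- matrix(0.5, 3, 3)
  diag(A) <- 1
  dimnames(A) <- list(letters[1:3], letters[1:3])
  expect_equal(tom_similarity(A)[1, 2], 0.5)

  A0 <- diag(4)
  expect_equal(unname(tom_similarity(A0)), diag(4))

  tom_oracle <- function(A) {
    n <- nrow(A)
    k <- rowSums(A) - diag(A)
    T <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      T[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
    T
  }
  for (s in 1:20) {
    set.seed(s)
    C <- cor(matrix(rnorm(10 * 12), 12, 10))
    A <- signed_adjacency(C, 6)
    expect_equal(unname(tom_similarity(A)), tom_oracle(A), tolerance = 1e-12)
  }
})

test_that("block-diagonal structure yields exact module recovery", {
  X <- make_block_matrix(n_per_block = 50, noise_sd = 0, seed = 2)
  A <- signed_adjacency(bicor_matrix(X), 12)
  tom <- tom_similarity(A)
  cfg <- network_config(min_module_size = 30)
  det <- detect_modules(tom, cfg, expr = X)
  expect_equal(length(det$module_sizes), 2L)
  lab <- det$module_of_gene
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_false(lab[1] == lab[51])

  # min_module_size beyond every cluster: everything unassigned
  set.seed(2)
  X3 <- do.call(rbind, lapply(1:3, function(b) {
    matrix(rep(rnorm(20), each = 50), 50, 20)
  }))
  dimnames(X3) <- list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:20))
  tom3 <- tom_similarity(signed_adjacency(bicor_matrix(X3), 12))
  cfg_big <- network_config(min_module_size = 60, pam_stage = FALSE,
                            cut_height_quantile = 0.5)
  det_big <- detect_modules(tom3, cfg_big)
  expect_true(all(det_big$module_of_gene == "UNASSIGNED"))
})

test_that("eigengenes are unit-variance, oriented, PC1 profiles", {
  X <- make_block_matrix(n_per_block = 40, noise_sd = 0.2, seed = 3)
  lab <- setNames(rep(c("M1", "M2"), each = 40), rownames(X))
  E <- module_eigengenes(X, lab)
  expect_equal(apply(E, 1, sd), c(M1 = 1, M2 = 1), tolerance = 1e-10)
  kme <- kme_matrix(X, E, method = "pearson")
  expect_gt(mean(kme[1:40, "M1"]), 0)
  expect_gt(mean(kme[41:80, "M2"]), 0)

  # identical genes: eigengene equals the standardized common profile
  Xid <- matrix(rep(rnorm(15), each = 5), 5, 15,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:15)))
  Eid <- module_eigengenes(Xid, setNames(rep("M1", 5), rownames(Xid)))
  prof <- (Xid[1, ] - mean(Xid[1, ])) / sd(Xid[1, ])
  expect_equal(abs(cor(Eid[1, ], prof)), 1, tolerance = 1e-10)
  expect_equal(unname(kme_matrix(Xid, Eid, method = "pearson")[, 1]),
               rep(1, 5), tolerance = 1e-10)

  # flipping all module genes flips the oriented eigengene, preserving the
  # non-negative mean-kME orientation invariant
  Eflip <- module_eigengenes(-X, lab)
  expect_equal(E, -Eflip, tolerance = 1e-10)
  kme_flip <- kme_matrix(-X, Eflip, method = "pearson")
  expect_gt(mean(kme_flip[1:40, "M1"]), 0)

  # explained variance matches an SVD oracle
  sub <- X[1:40, ]
  Z <- t(scale(t(sub)))
  d <- svd(Z)$d
  expect_equal(unname(attr(E, "var_explained")["M1"]), d[1]^2 / sum(d^2),
               tolerance = 1e-10)

  expect_error(module_eigengenes(X, setNames(c("M1", "M1", rep("UNASSIGNED", 78)),
                                             rownames(X))), "fewer than 3")
})

test_that("iterative detection converges without pruning on clean blocks", {
  X <- make_block_matrix(n_per_block = 40, noise_sd = 0, seed = 4)
  res <- iterative_wgcna(X, network_config(min_module_size = 30))
  expect_true(res$converged)
  expect_lte(res$n_iterations, 2L)
  expect_true(all(res$assignment$module_of_gene != "UNASSIGNED"))
  expect_equal(length(res$assignment$module_sizes), 2L)
})

test_that("pure-noise genes end unassigned and median kME is high", {
  X <- make_block_matrix(n_per_block = 50, n_noise = 100, noise_sd = 0.2,
                         seed = 5)
  res <- iterative_wgcna(X, network_config(min_module_size = 30))
  lab <- res$assignment$module_of_gene
  noise_genes <- rownames(X)[101:200]
  expect_gte(mean(lab[noise_genes] == "UNASSIGNED"), 0.9)

  sel <- select_modules(res$kme, res$assignment)
  expect_true(all(sel$median_kme > 0.8))
})

test_that("a zero pruning threshold reduces to a single detection pass", {
  X <- make_block_matrix(n_per_block = 40, n_noise = 30, noise_sd = 0.3,
                         seed = 6)
  cfg <- network_config(min_module_size = 30, mm_prune_threshold = 0)
  res <- iterative_wgcna(X, cfg)
  A <- signed_adjacency(bicor_matrix(X), cfg$beta)
  det <- detect_modules(tom_similarity(A), cfg, expr = X)
  expect_equal(res$assignment$module_of_gene, det$module_of_gene)
})

test_that("assignment is invariant to gene order and positive affine scaling", {
  X <- make_block_matrix(n_per_block = 40, n_noise = 40, noise_sd = 0.25,
                         seed = 7)
  cfg <- network_config(min_module_size = 30)
  res1 <- iterative_wgcna(X, cfg)
  set.seed(8)
  perm <- sample(nrow(X))
  res2 <- iterative_wgcna(X[perm, ], cfg)
  skip_if_not_installed("mclust")
  lab1 <- res1$assignment$module_of_gene
  lab2 <- res2$assignment$module_of_gene[names(lab1)]
  # same partition (labels may be renamed)
  expect_equal(mclust::adjustedRandIndex(lab1, lab2), 1)

  scale_fac <- runif(nrow(X), 0.5, 3)
  res3 <- iterative_wgcna(X * scale_fac + rnorm(nrow(X)), cfg)
  expect_equal(lab1, res3$assignment$module_of_gene)
})
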