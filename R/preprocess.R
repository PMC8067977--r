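#' Summarize probes to genes by maximal interquartile range
#'
#' When several probes interrogate the same gene, the probe with the maximal
#' IQR across samples is retained as the gene's representative row; ties are
#' broken by lexicographic probe id. Unmapped probes are dropped.
#'
#' @param probes probe-level log2 matrix (probes x samples, rownames = probe
#'   ids).
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`; every
#'   probe maps to at most one gene.
#' @return gene-level matrix (rownames = gene ids).
#' @export
summarize_probes <- function(probes, probe_to_gene) {
  stopifnot(is.matrix(probes), !is.null(rownames(probes)))
  if (!all(c("probe_id", "gene_id") %in% names(probe_to_gene)) ||
      nrow(probe_to_gene) == 0) {
    stop("probe_to_gene must be a non-empty data.frame with probe_id and gene_id")
  }
  if (anyDuplicated(probe_to_gene$probe_id)) {
    stop("every probe must map to at most one gene")
  }
  map <- probe_to_gene[probe_to_gene$probe_id %in% rownames(probes), , drop = FALSE]
  if (nrow(map) == 0) stop("no mapped probes present in the matrix")
  iqr <- apply(probes[map$probe_id, , drop = FALSE], 1L, stats::IQR)
  # order by gene, then decreasing IQR, then probe id: first row per gene wins
  ord <- order(map$gene_id, -iqr, map$probe_id)
  map <- map[ord, , drop = FALSE]
  sel <- map[!duplicated(map$gene_id), , drop = FALSE]
  out <- probes[sel$probe_id, , drop = FALSE]
  rownames(out) <- sel$gene_id
  out[order(rownames(out)), , drop = FALSE]
}

#' Fit a two-component Gaussian mixture to pooled expression values
#'
#' Models the pooled log2 expression distribution as a mixture of a low
#' (background) and a high (expressed) Gaussian, fitted by EM with free
#' means, variances and weights. The low-expression threshold is the
#' smallest point between the two component means at which the posterior
#' probability of the high component reaches 0.5, i.e. the point from which
#' on a value is more likely to come from the expressed component.
#'
#' @param values numeric vector of pooled log2 expression values (>= 100,
#'   nonzero spread).
#' @param seed seed for the k-means initialization.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return an object of class `two_gaussian_fit` with fields `mu_low`,
#'   `mu_high`, `sigma_low`, `sigma_high`, `weight_low`, `threshold`,
#'   `converged`, `n_iterations`, `loglik`.
#' @export
fit_two_gaussian <- function(values, seed = 1L, max_iter = 500L, tol = 1e-8) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 100L) stop("need at least 100 finite values")
  if (stats::sd(values) == 0) stop("values have zero spread; cannot fit a mixture")

  set.seed(seed)
  km <- stats::kmeans(values, centers = 2L, nstart = 1L)
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  sg <- vapply(ord, function(k) {
    s <- stats::sd(values[km$cluster == k])
    if (!is.finite(s) || s < 1e-6) 1e-6 else s
  }, numeric(1))
  w <- as.numeric(table(factor(km$cluster, levels = ord))) / length(values)
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)

  loglik <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(values, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g1 <- d1 / tot
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- sum(g2)
    mu <- c(sum(g1 * values) / n1, sum(g2 * values) / n2)
    sg <- sqrt(c(sum(g1 * (values - mu[1])^2) / n1,
                 sum(g2 * (values - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-6)
    w <- c(n1, n2) / length(values)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter, " iterations; best fit returned")
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w)
  }

  # posterior-0.5 crossing of the high component, searched on a fine grid
  grid <- seq(mu[1], mu[2], length.out = 2001L)
  post_high <- w[2] * stats::dnorm(grid, mu[2], sg[2]) /
    (w[1] * stats::dnorm(grid, mu[1], sg[1]) +
       w[2] * stats::dnorm(grid, mu[2], sg[2]))
  hit <- which(post_high >= 0.5)
  threshold <- if (length(hit)) grid[hit[1]] else mu[2]

  structure(list(mu_low = mu[1], mu_high = mu[2],
                 sigma_low = sg[1], sigma_high = sg[2],
                 weight_low = w[1], threshold = threshold,
                 converged = converged, n_iterations = it, loglik = loglik),
            class = "two_gaussian_fit")
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-Gaussian fit: low N(%.3f, %.3f), high N(%.3f, %.3f), ",
                     "weight_low %.3f\nthreshold %.3f (%s in %d iterations)\n"),
              x$mu_low, x$sigma_low, x$mu_high, x$sigma_high, x$weight_low,
              x$threshold, if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Remove genes below the expressed-component threshold in all samples
#'
#' Retains exactly the genes whose maximum over samples is at least the
#' fitted threshold; a gene below the threshold in every sample is excluded.
#'
#' @param X genes x samples log2 matrix.
#' @param fit a [fit_two_gaussian()] result, or a single numeric threshold.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(X, fit) {
  thr <- if (inherits(fit, "two_gaussian_fit")) fit$threshold else as.numeric(fit)
  stopifnot(is.matrix(X), length(thr) == 1L, is.finite(thr))
  keep <- apply(X, 1L, max) >= thr
  if (!any(keep)) stop("threshold removes every gene")
  X[keep, , drop = FALSE]
}

#' Sample-network outlier detection by z-normalized connectivity (zK)
#'
#' Computes each sample's connectivity `k_i = sum_{j != i} cor(sample_i,
#' sample_j)`, standardizes it to zK across samples, and flags samples with
#' `zK < -zk_threshold` (one-sided by default; low connectivity means the
#' sample does not co-vary with the rest of the cohort).
#'
#' @param X genes x samples matrix (>= 4 samples).
#' @param zk_threshold exclusion threshold on zK (default 1.96).
#' @param cor_method correlation used between samples ("pearson" default).
#' @param two_sided if TRUE, also exclude zK > zk_threshold.
#' @return an object of class `outlier_report`: `zk` (named per-sample),
#'   `excluded_samples`, `zk_threshold`, `two_sided`.
#' @export
sample_outliers <- function(X, zk_threshold = 1.96,
                            cor_method = c("pearson", "spearman"),
                            two_sided = FALSE) {
  cor_method <- match.arg(cor_method)
  stopifnot(is.matrix(X), ncol(X) >= 4L)
  sds <- apply(X, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(X, method = cor_method))
  if (any(sds == 0)) {
    warning("constant sample(s) detected; their correlations are set to 0")
    C[sds == 0, ] <- 0
    C[, sds == 0] <- 0
  }
  diag(C) <- 0
  k <- colSums(C)
  sk <- stats::sd(k)
  if (!is.finite(sk) || sk == 0) {
    zk <- stats::setNames(rep(0, length(k)), colnames(X))
    excluded <- character(0)
  } else {
    zk <- (k - mean(k)) / sk
    names(zk) <- colnames(X)
    excluded <- names(zk)[if (two_sided) abs(zk) > zk_threshold else zk < -zk_threshold]
  }
  structure(list(zk = zk, excluded_samples = excluded,
                 zk_threshold = zk_threshold, two_sided = two_sided),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("zK outlier report: %d samples, %d excluded (%s zK threshold %.2f)\n",
              length(x$zk), length(x$excluded_samples),
              if (x$two_sided) "two-sided" else "one-sided", x$zk_threshold))
  if (length(x$excluded_samples)) {
    cat("excluded:", paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}
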