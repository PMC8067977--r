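#' Design specification for the paired 2x2 comparison
#'
#' Concatenates cell origin and activation into a single 4-level `group`
#' factor (NECneg, NECpos, TECneg, TECpos), records the subject id as the
#' blocking variable, and carries the named contrasts of interest (each a
#' length-4 weight vector over the group levels, summing to zero).
#'
#' @param annotation sample annotation with `subject_id`, `origin`,
#'   `activation` (see [simulate_cohort()]).
#' @param contrasts named list of length-4 numeric contrast vectors; default
#'   is the four tumour-vs-non-tumour and ENG+-vs-ENG- comparisons.
#' @return an object of class `design_spec` with fields `group`, `block`,
#'   `levels`, `contrasts`, `design` (the 0+group model matrix).
#' @export
design_spec <- function(annotation, contrasts = NULL) {
  stopifnot(all(c("subject_id", "origin", "activation") %in% names(annotation)))
  tag <- paste0(ifelse(annotation$origin == "tumour", "TEC", "NEC"),
                ifelse(annotation$activation == "ENGpos", "pos", "neg"))
  levels <- c("NECneg", "NECpos", "TECneg", "TECpos")
  group <- factor(tag, levels = levels)
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- levels
  rownames(design) <- annotation$sample_id
  if (is.null(contrasts)) {
    contrasts <- list(
      TECneg_vs_NECneg = c(-1, 0, 1, 0),
      TECpos_vs_NECpos = c(0, -1, 0, 1),
      NECpos_vs_NECneg = c(-1, 1, 0, 0),
      TECpos_vs_TECneg = c(0, 0, -1, 1)
    )
  }
  for (nm in names(contrasts)) {
    v <- contrasts[[nm]]
    if (length(v) != length(levels) || abs(sum(v)) > 1e-12) {
      stop("contrast '", nm, "' must have length 4 and weights summing to 0")
    }
  }
  structure(list(group = group,
                 block = as.character(annotation$subject_id),
                 levels = levels, contrasts = contrasts, design = design),
            class = "design_spec")
}

# per-block compound-symmetry helpers: quadratic form and log-determinant of
# V = (1-rho) I + rho J at unit scale
.cs_quadform <- function(ss, s, m, rho) {
  sum((ss - rho / (1 + (m - 1) * rho) * s^2) / (1 - rho))
}
.cs_logdet <- function(m, rho) {
  sum((m - 1) * log(1 - rho) + log(1 + (m - 1) * rho))
}

#' Consensus within-block correlation for a blocked design
#'
#' Estimates, for every gene, the within-subject correlation under a
#' random-intercept model fitted by REML to the residuals of the group-means
#' fit, and summarizes the per-gene estimates into a single consensus value
#' by a 10% trimmed mean on the atanh scale, clamped to (-0.99, 0.99).
#'
#' @param X genes x samples log2 matrix.
#' @param design a [design_spec()] object.
#' @param trim trimming fraction for the consensus mean.
#' @return a single numeric consensus correlation.
#' @export
estimate_consensus_correlation <- function(X, design, trim = 0.1) {
  stopifnot(is.matrix(X), inherits(design, "design_spec"),
            ncol(X) == length(design$group))
  blocks <- split(seq_along(design$block), design$block)
  if (all(lengths(blocks) == 1L)) {
    warning("all blocks are singletons; consensus correlation is 0")
    return(0)
  }
  # residuals from the per-group means fit
  R <- X
  for (lv in levels(design$group)) {
    idx <- which(design$group == lv)
    if (length(idx)) R[, idx] <- X[, idx, drop = FALSE] - rowMeans(X[, idx, drop = FALSE])
  }
  m <- lengths(blocks)
  n <- ncol(X)
  rho_gene <- apply(R, 1L, function(r) {
    s <- vapply(blocks, function(i) sum(r[i]), numeric(1))
    ss <- vapply(blocks, function(i) sum(r[i]^2), numeric(1))
    if (sum(ss) == 0) return(0)
    nll <- function(rho) {
      q <- .cs_quadform(ss, s, m, rho)
      n * log(q / n) + .cs_logdet(m, rho)
    }
    stats::optimize(nll, c(0, 0.98))$minimum
  })
  cons <- tanh(mean(atanh(pmin(pmax(rho_gene, -0.99), 0.99)), trim = trim))
  min(max(cons, -0.99), 0.99)
}

#' Generalized least squares fit of per-group means with block correlation
#'
#' Fits, gene by gene, the model `expression ~ 0 + group` by GLS under a
#' within-block equicorrelation (compound symmetry) structure with
#' correlation `rho`; at `rho = 0` this reduces to ordinary per-group means.
#'
#' @param X genes x samples matrix.
#' @param design a [design_spec()] object.
#' @param rho within-block correlation, typically from
#'   [estimate_consensus_correlation()].
#' @return an object of class `moderated_fit` holding per-gene coefficients,
#'   residual variances `sigma2`, residual df, `rho`, the unscaled
#'   coefficient covariance, and the design.
#' @export
fit_group_means <- function(X, design, rho = 0) {
  stopifnot(is.matrix(X), inherits(design, "design_spec"),
            ncol(X) == length(design$group), abs(rho) < 1)
  D <- design$design
  if (qr(D)$rank < ncol(D)) stop("design matrix is rank deficient")
  n <- nrow(D)
  V <- diag(n)
  for (idx in split(seq_len(n), design$block)) {
    V[idx, idx] <- rho
  }
  diag(V) <- 1
  Vi <- solve(V)
  A <- crossprod(D, Vi %*% D)          # X' V^-1 X
  cov_unscaled <- solve(A)
  M <- Vi %*% D %*% cov_unscaled       # V^-1 X (X'V^-1X)^-1
  coef <- X %*% M                      # genes x 4
  resid <- X - coef %*% t(D)
  df <- n - ncol(D)
  sigma2 <- rowSums((resid %*% Vi) * resid) / df
  structure(list(coefficients = coef, sigma2 = sigma2, df_residual = df,
                 rho = rho, cov_unscaled = cov_unscaled, design = design,
                 gene_ids = rownames(X)),
            class = "moderated_fit")
}

# Newton inversion of the trigamma function (solves trigamma(y) = x)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# moment matching of a scaled inverse-chi-square prior on the residual
# variances, via the distribution of log s^2
.squeeze_var <- function(sigma2, df) {
  s2 <- pmax(sigma2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s0_2 + df * s2) / (d0 + df)
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
    post <- rep(s0_2, length(s2))
  }
  list(df_prior = d0, var_prior = s0_2, var_post = post)
}

#' Moderated t-statistics for a contrast with empirical-Bayes shrinkage
#'
#' Estimates the prior degrees of freedom and prior variance by moment
#' matching on the log residual variances, shrinks the per-gene variances
#' towards the prior, and tests the requested contrast with moderated
#' t-statistics on `df + d0` degrees of freedom. P-values are adjusted with
#' Benjamini-Hochberg by default; a gene is flagged differentially expressed
#' when `|log2FC| > lfc_threshold` and the adjusted p-value is below `alpha`.
#'
#' @param fit a [fit_group_means()] result.
#' @param contrast name of a contrast in the design, or a length-4 weight
#'   vector.
#' @param lfc_threshold absolute log2 fold-change threshold (default 2).
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param adjust p-value adjustment method (default "BH").
#' @return a data.frame: gene_id, log2FC, t, p, p_adj, de; attributes
#'   `df_prior`, `var_prior`, `df_total`.
#' @export
moderate_and_test <- function(fit, contrast, lfc_threshold = 2, alpha = 0.05,
                              adjust = c("BH", "hochberg", "holm", "bonferroni", "none")) {
  stopifnot(inherits(fit, "moderated_fit"))
  adjust <- match.arg(adjust)
  cv <- if (is.character(contrast)) {
    if (!contrast %in% names(fit$design$contrasts)) {
      stop("unknown contrast '", contrast, "'")
    }
    fit$design$contrasts[[contrast]]
  } else as.numeric(contrast)
  stopifnot(length(cv) == ncol(fit$coefficients))

  lfc <- as.numeric(fit$coefficients %*% cv)
  se_unscaled <- sqrt(as.numeric(t(cv) %*% fit$cov_unscaled %*% cv))
  n_genes <- length(fit$sigma2)
  if (n_genes < 10L) {
    warning("fewer than 10 genes; no variance moderation applied (d0 = 0)")
    sq <- list(df_prior = 0, var_prior = NA_real_, var_post = pmax(fit$sigma2, 1e-12))
  } else {
    sq <- .squeeze_var(fit$sigma2, fit$df_residual)
  }
  df_total <- fit$df_residual + sq$df_prior
  tstat <- lfc / (sqrt(sq$var_post) * se_unscaled)
  p <- 2 * stats::pt(-abs(tstat), df = min(df_total, 1e7))
  p_adj <- stats::p.adjust(p, method = adjust)
  out <- data.frame(gene_id = fit$gene_ids %||% seq_len(n_genes),
                    log2FC = lfc, t = tstat, p = p, p_adj = p_adj,
                    de = abs(lfc) > lfc_threshold & p_adj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  attr(out, "df_total") <- df_total
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
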