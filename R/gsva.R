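#' Gene-level rank statistics for single-sample gene-set scoring
#'
#' For every gene, the expression values are normalised across samples by a
#' Gaussian-kernel cumulative density estimate (bandwidth = per-gene SD / 4);
#' within every sample, genes are then ranked by decreasing kernel-CDF score
#' and converted to the symmetric rank statistic `|r - (n_genes + 1)/2|`,
#' which up-weights genes at either extreme of the sample's ranking.
#'
#' @param X genes x samples log2 matrix (>= 3 samples).
#' @return an object of class `gsva_stats`: `kcdf` (genes x samples kernel
#'   CDF scores), `ranks` (genes x samples, 1 = highest score), `statistic`
#'   (symmetric rank statistics), `bandwidths` (per-gene).
#' @export
gene_level_statistics <- function(X) {
  stopifnot(is.matrix(X), ncol(X) >= 3L, !is.null(rownames(X)))
  n_genes <- nrow(X)
  n_samp <- ncol(X)
  bw <- apply(X, 1L, stats::sd) / 4
  if (any(bw == 0)) {
    warning(sum(bw == 0), " constant gene(s); their statistic is uniform")
  }
  Z <- matrix(0, n_genes, n_samp, dimnames = dimnames(X))
  for (i in seq_len(n_genes)) {
    if (bw[i] == 0) {
      Z[i, ] <- 0.5
    } else {
      Z[i, ] <- rowMeans(stats::pnorm(outer(X[i, ], X[i, ], "-") / bw[i]))
    }
  }
  # rank genes within each sample by decreasing score; ties broken by gene id
  # so that the result is invariant to the input row ordering
  id_rank <- rank(rownames(X), ties.method = "first")
  R <- apply(-Z, 2L, function(z) {
    ord <- order(z, id_rank)
    r <- integer(n_genes)
    r[ord] <- seq_len(n_genes)
    r
  })
  dimnames(R) <- dimnames(X)
  S <- abs(R - (n_genes + 1) / 2)
  structure(list(kcdf = Z, ranks = R, statistic = S, bandwidths = bw),
            class = "gsva_stats")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, gene ids).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a named list of gene sets to GMT
#'
#' @param genesets named list of gene-id vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(genesets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(genesets))
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample gene-set scores from a weighted random walk
#'
#' For each sample, genes are ordered by decreasing kernel-CDF score and a
#' random walk is taken down the ranking: in-set genes step up by their
#' symmetric rank statistic raised to `tau` (normalised over the set),
#' out-of-set genes step down uniformly. The score is the sum of the largest
#' positive and the largest negative deviation of the walk, giving a value
#' in [-1, 1]; positive scores indicate coordinated over-expression of the
#' set in that sample. A set covering every gene has no outside steps and
#' scores 0 by definition. Sets overlapping the matrix in fewer than
#' `min_overlap` genes are dropped with a message.
#'
#' @param stats a [gene_level_statistics()] result.
#' @param collection named list of gene-id vectors (see [read_gmt()]).
#' @param tau exponent on the rank statistic (default 1).
#' @param min_overlap minimum genes a set must share with the matrix.
#' @return an object of class `gsva_scores`: `scores` (sets x samples) plus
#'   the per-set overlap counts.
#' @export
score_sets <- function(stats, collection, tau = 1, min_overlap = 2L) {
  stopifnot(inherits(stats, "gsva_stats"))
  if (length(collection) == 0) stop("empty gene-set collection")
  genes <- rownames(stats$kcdf)
  n_genes <- length(genes)
  n_samp <- ncol(stats$kcdf)
  overlap <- vapply(collection, function(g) sum(unique(g) %in% genes), integer(1))
  dropped <- names(collection)[overlap < min_overlap]
  if (length(dropped)) {
    message(length(dropped), " set(s) dropped (overlap < ", min_overlap, "): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  keep <- names(collection)[overlap >= min_overlap]
  scores <- matrix(0, length(keep), n_samp,
                   dimnames = list(keep, colnames(stats$kcdf)))
  member <- lapply(collection[keep], function(g) genes %in% g)
  for (j in seq_len(n_samp)) {
    ord <- order(stats$ranks[, j])      # position 1 = top-ranked gene
    sj <- stats$statistic[, j]^tau
    for (si in seq_along(keep)) {
      inset <- member[[si]][ord]
      n_in <- sum(inset)
      if (n_in == n_genes) next         # no contrast: score 0
      up <- sj[ord] * inset
      up <- up / sum(up)
      down <- (!inset) / (n_genes - n_in)
      v <- cumsum(up - down)
      scores[si, j] <- max(0, max(v)) + min(0, min(v))
    }
  }
  structure(list(scores = scores, overlap = overlap[keep],
                 dropped = dropped, tau = tau),
            class = "gsva_scores")
}

#' Differential pathway analysis on a gene-set score matrix
#'
#' Reuses the moderated blocked linear model on the set x sample score
#' matrix: consensus correlation, GLS group means, variance moderation and
#' BH-adjusted moderated t-statistics per contrast, together with the raw
#' group score difference. Constant score rows are excluded with a warning.
#'
#' @param scores a [score_sets()] result (or a sets x samples matrix).
#' @param design a [design_spec()] object.
#' @param contrast contrast name or weight vector (see [moderate_and_test()]).
#' @param rho consensus correlation; estimated from the scores when NULL.
#' @return data.frame: set, score_diff, t, p, p_adj, de; `de` uses the score
#'   difference sign only (no fold-change threshold applies to scores).
#' @export
differential_pathways <- function(scores, design, contrast, rho = NULL) {
  S <- if (inherits(scores, "gsva_scores")) scores$scores else scores
  stopifnot(is.matrix(S), inherits(design, "design_spec"))
  constant <- apply(S, 1L, stats::sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant score row(s) excluded")
    S <- S[!constant, , drop = FALSE]
  }
  if (nrow(S) == 0) stop("no non-constant score rows")
  if (is.null(rho)) {
    rho <- if (nrow(S) >= 5) estimate_consensus_correlation(S, design) else 0
  }
  fit <- fit_group_means(S, design, rho = rho)
  res <- moderate_and_test(fit, contrast, lfc_threshold = 0)
  data.frame(set = rownames(S), score_diff = res$log2FC, t = res$t,
             p = res$p, p_adj = res$p_adj, de = res$p_adj < 0.05,
             stringsAsFactors = FALSE)
}
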