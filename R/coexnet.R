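#' Network construction and module detection configuration
#'
#' Defaults follow the signed weighted network parameterization used for
#' microarray co-expression analysis: soft threshold beta = 12, biweight
#' midcorrelation, deepsplit 2, PAM-style adoption of unassigned genes,
#' minimum module size 30 and a module-membership pruning threshold of 0.8
#' for the iterative detection loop.
#'
#' @param beta positive integer soft-threshold exponent.
#' @param correlation "bicor" (robust, default) or "pearson".
#' @param min_module_size smallest retained module.
#' @param deepsplit integer 0-4 controlling how deep the dendrogram is cut;
#'   maps to a merge-height quantile of c(0.999, 0.995, 0.99, 0.98, 0.95).
#' @param pam_stage adopt unassigned genes into the closest module when
#'   their kME reaches `mm_prune_threshold`.
#' @param mm_prune_threshold module-membership (kME) threshold used both for
#'   pruning in the iterative loop and for PAM adoption.
#' @param max_iterations cap on iterative detect/prune cycles.
#' @param cut_height_quantile override for the deepsplit-derived quantile.
#' @param max_genes guard on the dense-matrix gene count.
#' @return an object of class `network_config`.
#' @export
network_config <- function(beta = 12L,
                           correlation = c("bicor", "pearson"),
                           min_module_size = 30L,
                           deepsplit = 2L,
                           pam_stage = TRUE,
                           mm_prune_threshold = 0.8,
                           max_iterations = 10L,
                           cut_height_quantile = NULL,
                           max_genes = 20000L) {
  correlation <- match.arg(correlation)
  stopifnot(beta >= 1, deepsplit %in% 0:4,
            mm_prune_threshold >= 0, mm_prune_threshold < 1,
            min_module_size >= 2, max_iterations >= 1)
  if (is.null(cut_height_quantile)) {
    cut_height_quantile <- c(0.999, 0.995, 0.99, 0.98, 0.95)[deepsplit + 1L]
  }
  structure(list(beta = as.integer(beta), correlation = correlation,
                 network_type = "signed",
                 min_module_size = as.integer(min_module_size),
                 deepsplit = as.integer(deepsplit), pam_stage = pam_stage,
                 mm_prune_threshold = mm_prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 cut_height_quantile = cut_height_quantile,
                 max_genes = as.integer(max_genes)),
            class = "network_config")
}

# rows of X median-centered, biweight-weighted and scaled to unit norm, so
# that bicor is a plain cross product of normalized rows; rows with MAD = 0
# fall back to the analogous Pearson normalization
.bicor_normalize <- function(X) {
  med <- apply(X, 1L, stats::median)
  madv <- apply(X, 1L, function(x) stats::mad(x, constant = 1))
  D <- X - med
  U <- D / (9 * madv)
  W <- (1 - U^2)^2 * (abs(U) < 1)
  A <- D * W
  fallback <- madv == 0
  if (any(fallback)) {
    D2 <- X[fallback, , drop = FALSE] -
      rowMeans(X[fallback, , drop = FALSE])
    A[fallback, ] <- D2
  }
  nrm <- sqrt(rowSums(A^2))
  nrm[nrm == 0] <- 1
  A / nrm
}

#' Biweight midcorrelation
#'
#' Robust correlation based on median-centering and Tukey biweights with the
#' standard tuning constant of 9 times the median absolute deviation:
#' `u = (x - median(x)) / (9 * mad(x))`, weights `w = (1 - u^2)^2` for
#' `|u| < 1` and 0 otherwise. When a vector's MAD is 0 the computation falls
#' back to Pearson for that vector.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  stopifnot(length(x) >= 3)
  N <- .bicor_normalize(rbind(x, y))
  min(max(sum(N[1, ] * N[2, ]), -1), 1)
}

#' Biweight midcorrelation matrix between the rows of a matrix
#'
#' @param X variables x observations matrix.
#' @param Y optional second matrix; when given, the cross-correlation
#'   (rows of X vs rows of Y) is returned.
#' @return correlation matrix in [-1, 1].
#' @export
bicor_matrix <- function(X, Y = NULL) {
  stopifnot(is.matrix(X), ncol(X) >= 3)
  Nx <- .bicor_normalize(X)
  C <- if (is.null(Y)) tcrossprod(Nx) else {
    stopifnot(is.matrix(Y), ncol(Y) == ncol(X))
    tcrossprod(Nx, .bicor_normalize(Y))
  }
  pmin(pmax(C, -1), 1)
}

# correlation dispatch used by the network code
.cor_rows <- function(X, Y = NULL, method = "bicor") {
  if (method == "bicor") {
    bicor_matrix(X, Y)
  } else if (is.null(Y)) {
    C <- suppressWarnings(stats::cor(t(X)))
    C[!is.finite(C)] <- 0
    C
  } else {
    C <- suppressWarnings(stats::cor(t(X), t(Y)))
    C[!is.finite(C)] <- 0
    C
  }
}

#' Signed weighted adjacency from a correlation matrix
#'
#' `a_ij = ((1 + c_ij) / 2)^beta`, mapping correlation -1 to adjacency 0 and
#' +1 to 1, so that only positively correlated genes remain connected after
#' soft thresholding.
#'
#' @param C correlation matrix with entries in [-1, 1].
#' @param beta soft-threshold exponent.
#' @return adjacency matrix in [0, 1] with unit diagonal.
#' @export
signed_adjacency <- function(C, beta = 12L) {
  stopifnot(is.matrix(C), min(C) >= -1 - 1e-12, max(C) <= 1 + 1e-12, beta >= 1)
  A <- ((1 + pmin(pmax(C, -1), 1)) / 2)^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{u != i} a_iu`; two genes are topologically similar when
#' they are connected and share neighbours. Diagonal is 1.
#'
#' @param A adjacency matrix (symmetric, entries in [0, 1]).
#' @return TOM matrix in [0, 1].
#' @export
tom_similarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  Ad <- A
  diag(Ad) <- 0
  L <- Ad %*% Ad                       # excludes u = i and u = j (zero diag)
  k <- rowSums(Ad)
  kmin <- outer(k, k, pmin)
  TOM <- (L + Ad) / (kmin + 1 - Ad)
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression submatrix, scaled to unit variance and
#' sign-oriented so that the mean correlation with the module's genes is
#' non-negative.
#'
#' @param X genes x samples matrix.
#' @param assignment named character vector gene -> module label (or a
#'   `module_assignment` object); label "UNASSIGNED" is skipped.
#' @return matrix modules x samples with attribute `var_explained`.
#' @export
module_eigengenes <- function(X, assignment) {
  labels <- if (inherits(assignment, "module_assignment")) {
    assignment$module_of_gene
  } else assignment
  mods <- setdiff(sort(unique(labels)), "UNASSIGNED")
  mods <- mods[order(as.numeric(sub("^M", "", mods)))]
  if (length(mods) == 0) stop("no assigned modules")
  E <- matrix(0, length(mods), ncol(X), dimnames = list(mods, colnames(X)))
  varex <- numeric(length(mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    if (length(genes) < 3) stop("module ", mods[i], " has fewer than 3 genes")
    sub <- X[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    sds[sds == 0] <- 1
    Z <- (sub - rowMeans(sub)) / sds
    sv <- svd(Z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(Z %*% e) < 0) e <- -e     # orient towards the genes
    if (stats::sd(e) > 0) e <- e / stats::sd(e)
    E[i, ] <- e
    varex[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(E, "var_explained") <- stats::setNames(varex, mods)
  E
}

#' Module membership (kME) of genes against module eigengenes
#'
#' @param X genes x samples matrix.
#' @param eigengenes modules x samples matrix from [module_eigengenes()].
#' @param method correlation estimator, matching the network's.
#' @return genes x modules kME matrix.
#' @export
kme_matrix <- function(X, eigengenes, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  .cor_rows(X, eigengenes, method = method)
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Clusters 1 - TOM by average linkage, cuts the tree at the configured
#' merge-height quantile, dissolves clusters below the minimum size to
#' UNASSIGNED, and (when `pam_stage` is on and expression is supplied)
#' adopts unassigned genes into the module whose eigengene they correlate
#' with most, provided that kME reaches the membership threshold. Retained
#' modules are labelled M1, M2, ... by decreasing size.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param config a [network_config()].
#' @param expr optional genes x samples matrix (same genes as `tom`),
#'   required for the PAM adoption stage.
#' @return an object of class `module_assignment`: `module_of_gene` (named
#'   vector, UNASSIGNED for unclustered genes), `module_sizes`, `cut_height`,
#'   `dendrogram` heights.
#' @export
detect_modules <- function(tom, config = network_config(), expr = NULL) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom), !is.null(rownames(tom)))
  if (nrow(tom) < 2 * config$min_module_size) {
    stop("need at least 2 * min_module_size genes")
  }
  d <- 1 - tom
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # adaptive cut: among candidate heights up to the deepsplit-derived
  # quantile cap, pick the one yielding the most clusters of at least
  # min_module_size (ties -> highest cut, i.e. the most conservative split)
  cap <- as.numeric(stats::quantile(hc$height, config$cut_height_quantile))
  cand <- unique(c(hc$height[hc$height <= cap], cap))
  cand <- sort(cand, decreasing = TRUE)
  if (length(cand) > 200L) {           # thin the grid on large trees
    cand <- cand[unique(round(seq(1L, length(cand), length.out = 200L)))]
  }
  cuts <- stats::cutree(hc, h = cand)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L)
  n_valid <- apply(cuts, 2L, function(cl) {
    sum(table(cl) >= config$min_module_size)
  })
  best <- which.max(n_valid)           # first = highest height on ties
  cut_height <- cand[best]
  raw <- cuts[, best]
  sizes <- table(raw)
  keep_ids <- as.integer(names(sizes)[sizes >= config$min_module_size])
  labels <- rep("UNASSIGNED", nrow(tom))
  names(labels) <- rownames(tom)
  if (length(keep_ids)) {
    # order retained clusters by decreasing size, then first gene, for
    # deterministic M1, M2, ... labelling
    first_gene <- vapply(keep_ids, function(id) min(which(raw == id)), integer(1))
    ord <- order(-as.integer(sizes[as.character(keep_ids)]), first_gene)
    for (r in seq_along(ord)) {
      labels[raw == keep_ids[ord[r]]] <- paste0("M", r)
    }
  }
  if (config$pam_stage && !is.null(expr) && any(labels != "UNASSIGNED") &&
      any(labels == "UNASSIGNED")) {
    E <- module_eigengenes(expr, labels)
    un <- names(labels)[labels == "UNASSIGNED"]
    kme <- kme_matrix(expr[un, , drop = FALSE], E, method = config$correlation)
    best <- max.col(kme, ties.method = "first")
    best_kme <- kme[cbind(seq_along(un), best)]
    adopt <- best_kme >= config$mm_prune_threshold
    labels[un[adopt]] <- rownames(E)[best[adopt]]
  }
  sizes_out <- table(labels[labels != "UNASSIGNED"])
  structure(list(module_of_gene = labels,
                 module_sizes = sizes_out,
                 cut_height = cut_height,
                 heights = hc$height),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n <- length(x$module_of_gene)
  cat(sprintf("Module assignment: %d genes, %d modules, %d unassigned\n",
              n, length(x$module_sizes), sum(x$module_of_gene == "UNASSIGNED")))
  if (length(x$module_sizes)) print(x$module_sizes)
  invisible(x)
}

#' Iterative module detection with module-membership pruning
#'
#' Repeats the cycle: build the signed network on the currently assigned
#' genes, detect modules, compute each gene's membership (kME, correlation
#' with its own module eigengene) and move genes with kME below the pruning
#' threshold to the unassigned pool -- until no gene falls below the
#' threshold (the assignment is stable) or `max_iterations` is reached.
#' Finally, previously pruned genes are re-adopted (best module first)
#' wherever their kME reaches the threshold; a threshold of 0 disables
#' pruning, reducing the loop to a single [detect_modules()] pass.
#'
#' @param X genes x samples matrix (filtered, outlier-free).
#' @param config a [network_config()].
#' @return list: `assignment` (a `module_assignment`), `eigengenes`
#'   (modules x samples), `kme` (all genes x modules), `converged`,
#'   `n_iterations`, `history` (per-iteration label snapshots).
#' @export
iterative_wgcna <- function(X, config = network_config()) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  if (nrow(X) > config$max_genes) {
    stop("gene count exceeds config$max_genes (", config$max_genes, ")")
  }
  all_genes <- rownames(X)
  current <- all_genes                 # genes carried into the network
  labels <- NULL
  history <- list()
  pruned_ever <- character(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(config$max_iterations)) {
    C <- .cor_rows(X[current, , drop = FALSE], method = config$correlation)
    A <- signed_adjacency(C, config$beta)
    tom <- tom_similarity(A)
    det <- detect_modules(tom, config, expr = X[current, , drop = FALSE])
    new_labels <- stats::setNames(rep("UNASSIGNED", length(all_genes)), all_genes)
    new_labels[current] <- det$module_of_gene[current]
    assigned <- names(new_labels)[new_labels != "UNASSIGNED"]
    if (length(assigned) == 0) {
      labels <- new_labels
      history[[it]] <- labels
      break
    }
    E <- module_eigengenes(X, new_labels)
    kme_all <- kme_matrix(X[assigned, , drop = FALSE], E,
                          method = config$correlation)
    kme_own <- kme_all[cbind(seq_along(assigned),
                             match(new_labels[assigned], rownames(E)))]
    # a zero threshold disables pruning (single-pass limit)
    prune <- if (config$mm_prune_threshold > 0) {
      assigned[kme_own < config$mm_prune_threshold]
    } else character(0)
    pruned_ever <- union(pruned_ever, prune)
    new_labels[prune] <- "UNASSIGNED"
    history[[it]] <- new_labels
    labels <- new_labels
    if (length(prune) == 0 ||
        (it > 1L && identical(history[[it - 1L]], new_labels))) {
      converged <- TRUE               # nothing left to prune: stable network
      break
    }
    current <- names(labels)[labels != "UNASSIGNED"]
    if (length(current) < 2 * config$min_module_size) break
  }

  mods <- setdiff(unique(labels), "UNASSIGNED")
  if (length(mods) == 0) {
    return(list(assignment = structure(list(module_of_gene = labels,
                                            module_sizes = table(character(0))),
                                       class = "module_assignment"),
                eigengenes = NULL, kme = NULL, converged = converged,
                n_iterations = it, history = history))
  }
  E <- module_eigengenes(X, labels)
  kme <- kme_matrix(X, E, method = config$correlation)

  # final re-adoption of previously pruned genes, best module first (genes
  # the detection stage itself left unassigned have already been through
  # the PAM adoption step each iteration)
  un <- intersect(names(labels)[labels == "UNASSIGNED"], pruned_ever)
  if (length(un)) {
    best <- max.col(kme[un, , drop = FALSE], ties.method = "first")
    best_kme <- kme[un, , drop = FALSE][cbind(seq_along(un), best)]
    adopt <- best_kme >= config$mm_prune_threshold
    labels[un[adopt]] <- colnames(kme)[best[adopt]]
  }
  assignment <- structure(list(module_of_gene = labels,
                               module_sizes = table(labels[labels != "UNASSIGNED"]),
                               converged = converged),
                          class = "module_assignment")
  list(assignment = assignment, eigengenes = E, kme = kme,
       converged = converged, n_iterations = it, history = history)
}
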