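#' Construct an ontology DAG object
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `type`
#'   (`is_a` or `part_of`); edges point child -> parent.
#' @return an object of class `ontology`.
#' @export
ontology <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent", "type") %in% names(edges)),
            all(edges$type %in% c("is_a", "part_of")),
            !anyDuplicated(terms$id),
            all(edges$child %in% terms$id), all(edges$parent %in% terms$id))
  # acyclicity check: Kahn's algorithm on the child -> parent arcs
  remaining <- terms$id
  ed <- edges
  repeat {
    removable <- remaining[!(remaining %in% ed$parent)]  # in-degree 0
    if (!length(removable)) break
    remaining <- setdiff(remaining, removable)
    ed <- ed[!(ed$child %in% removable), , drop = FALSE]
    if (!nrow(ed)) break
  }
  if (nrow(ed) > 0) stop("ontology edges contain a cycle")
  structure(list(terms = terms[, c("id", "name", "namespace")],
                 edges = edges[, c("child", "parent", "type")]),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d edges (%d is_a, %d part_of)\n",
              nrow(x$terms), nrow(x$edges), sum(x$edges$type == "is_a"),
              sum(x$edges$type == "part_of")))
  invisible(x)
}

#' Read a minimal OBO subset
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of`; obsolete terms are skipped.
#'
#' @param path OBO file.
#' @return an [ontology()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  idx <- which(lines == "[Term]")
  terms <- list(); edges <- list()
  bounds <- c(idx, length(lines) + 1L)
  for (b in seq_along(idx)) {
    chunk <- lines[idx[b]:(bounds[b + 1L] - 1L)]
    if (any(grepl("^is_obsolete: true", chunk))) next
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), chunk, value = TRUE))
      if (length(v)) v[1] else NA_character_
    }
    id <- get1("id")
    if (is.na(id)) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = get1("name"),
      namespace = get1("namespace") %||% "biological_process",
      stringsAsFactors = FALSE)
    isa <- sub(" !.*$", "", sub("^is_a: ", "", grep("^is_a: ", chunk, value = TRUE)))
    po <- grep("^relationship: part_of ", chunk, value = TRUE)
    po <- sub(" !.*$", "", sub("^relationship: part_of ", "", po))
    if (length(isa)) {
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = isa,
                                                type = "is_a", stringsAsFactors = FALSE)
    }
    if (length(po)) {
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = po,
                                                type = "part_of", stringsAsFactors = FALSE)
    }
  }
  ontology(do.call(rbind, terms),
           if (length(edges)) do.call(rbind, edges) else
             data.frame(child = character(0), parent = character(0),
                        type = character(0), stringsAsFactors = FALSE))
}

#' Write an ontology as a minimal OBO subset
#'
#' @param dag an [ontology()] object.
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", dag$terms$name[i]),
               paste0("namespace: ", dag$terms$namespace[i]))
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, if (e$type[j] == "is_a") {
        paste0("is_a: ", e$parent[j])
      } else {
        paste0("relationship: part_of ", e$parent[j])
      })
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

# ancestors (excluding the term itself) over both edge types
.ancestors <- function(dag, term) {
  out <- character(0)
  frontier <- term
  while (length(frontier)) {
    parents <- unique(dag$edges$parent[dag$edges$child %in% frontier])
    parents <- setdiff(parents, out)
    out <- c(out, parents)
    frontier <- parents
  }
  out
}

#' Propagate gene annotations up the ontology
#'
#' Closes a direct gene -> term annotation map over all ancestors, through
#' both `is_a` and `part_of` edges, so that a gene annotated to a leaf is
#' also counted at every ancestor up to the root. Idempotent.
#'
#' @param dag an [ontology()] object.
#' @param ann data.frame with columns `gene_id`, `term_id`.
#' @return data.frame `gene_id`, `term_id` (unique rows, sorted).
#' @export
propagate_annotations <- function(dag, ann) {
  stopifnot(inherits(dag, "ontology"),
            all(c("gene_id", "term_id") %in% names(ann)))
  unknown <- setdiff(unique(ann$term_id), dag$terms$id)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  anc <- lapply(unique(ann$term_id), function(t) c(t, .ancestors(dag, t)))
  names(anc) <- unique(ann$term_id)
  out <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    data.frame(gene_id = ann$gene_id[i], term_id = anc[[ann$term_id[i]]],
               stringsAsFactors = FALSE)
  }))
  out <- unique(out)
  out <- out[order(out$gene_id, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO over-representation test
#'
#' Tests every term within the size window for over-representation of the
#' module's genes against the analysed-gene background, with one-sided
#' upper-tail hypergeometric p-values and Benjamini-Hochberg adjustment.
#' Term sizes are evaluated on the background (propagated) annotation;
#' the [min_size, max_size] window is inclusive.
#'
#' @param module_genes character vector of gene ids (subset of background).
#' @param background character vector: all analysed genes.
#' @param ann propagated annotation data.frame (`gene_id`, `term_id`).
#' @param min_size,max_size inclusive term-size window (defaults 15, 500).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame per tested term: term_id, k, K, n, N, p, p_adj,
#'   neg_log10_padj, significant.
#' @export
enrich <- function(module_genes, background, ann,
                   min_size = 15L, max_size = 500L, alpha = 0.05) {
  module_genes <- unique(module_genes)
  background <- unique(background)
  if (length(module_genes) == 0) stop("empty module gene list")
  if (!all(module_genes %in% background)) {
    stop("module genes must be a subset of the background")
  }
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  term_genes <- split(ann$gene_id, ann$term_id)
  K <- lengths(lapply(term_genes, unique))
  tested <- names(K)[K >= min_size & K <= max_size]
  if (!length(tested)) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), neg_log10_padj = numeric(0),
                      significant = logical(0)))
  }
  N <- length(background)
  n <- length(module_genes)
  k <- vapply(tested, function(t) {
    sum(unique(term_genes[[t]]) %in% module_genes)
  }, integer(1))
  p <- stats::phyper(k - 1, K[tested], N - K[tested], n, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = tested, k = k, K = as.integer(K[tested]),
                    n = n, N = N, p = p, p_adj = p_adj,
                    neg_log10_padj = -log10(p_adj),
                    significant = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), ]
}

# S-values of all ancestors of `term` in its own ancestor graph:
# SV(term) = 1; SV(t) = max over children c of t (within the graph) of
# w(c -> t) * SV(c); computed by relaxation (converges on a DAG)
.svalues <- function(dag, term, w_isa = 0.8, w_partof = 0.6) {
  nodes <- c(term, .ancestors(dag, term))
  sv <- stats::setNames(rep(0, length(nodes)), nodes)
  sv[term] <- 1
  ed <- dag$edges[dag$edges$child %in% nodes & dag$edges$parent %in% nodes, ,
                  drop = FALSE]
  w <- ifelse(ed$type == "is_a", w_isa, w_partof)
  repeat {
    new <- sv[ed$parent]
    cand <- w * sv[ed$child]
    upd <- tapply(cand, ed$parent, max)
    changed <- FALSE
    for (p in names(upd)) {
      if (upd[[p]] > sv[p] + 1e-15) {
        sv[p] <- upd[[p]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sv
}

#' Wang graph-based semantic similarity between two ontology terms
#'
#' The semantic contribution of each ancestor decays along the path to the
#' term with edge weights 0.8 (`is_a`) and 0.6 (`part_of`); the similarity
#' of two terms is the summed contribution of their shared ancestors,
#' normalized by their total semantic values. Equals 1 for identical terms.
#'
#' @param dag an [ontology()] object.
#' @param t1,t2 term ids (must share a namespace).
#' @param w_isa,w_partof edge contribution weights.
#' @return similarity in (0, 1].
#' @export
wang_similarity <- function(dag, t1, t2, w_isa = 0.8, w_partof = 0.6) {
  stopifnot(inherits(dag, "ontology"))
  ns <- dag$terms$namespace[match(c(t1, t2), dag$terms$id)]
  if (anyNA(ns)) stop("unknown term id")
  if (ns[1] != ns[2]) stop("terms are in disjoint namespaces")
  sa <- .svalues(dag, t1, w_isa, w_partof)
  sb <- .svalues(dag, t2, w_isa, w_partof)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' Pairwise Wang similarity matrix
#'
#' @param dag an [ontology()] object.
#' @param terms character vector of term ids.
#' @inheritParams wang_similarity
#' @return symmetric similarity matrix.
#' @export
wang_similarity_matrix <- function(dag, terms, w_isa = 0.8, w_partof = 0.6) {
  sv <- lapply(terms, .svalues, dag = dag, w_isa = w_isa, w_partof = w_partof)
  names(sv) <- terms
  tot <- vapply(sv, sum, numeric(1))
  S <- diag(1, length(terms))
  dimnames(S) <- list(terms, terms)
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1L)) {
      for (j in (i + 1L):length(terms)) {
        common <- intersect(names(sv[[i]]), names(sv[[j]]))
        S[i, j] <- S[j, i] <-
          sum(sv[[i]][common] + sv[[j]][common]) / (tot[i] + tot[j])
      }
    }
  }
  S
}

# classic DBSCAN on a point matrix; returns integer labels with 0 = noise
.dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- rep(NA_integer_, n)        # NA = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (length(neighbours[[i]]) < min_pts) {
      labels[i] <- 0L                  # provisional noise; may become border
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(neighbours[[i]], i)
    while (length(seeds)) {
      q <- seeds[1]
      seeds <- seeds[-1]
      if (!is.na(labels[q]) && labels[q] == 0L) labels[q] <- cl  # border
      if (!is.na(labels[q])) next
      labels[q] <- cl
      if (length(neighbours[[q]]) >= min_pts) {
        claimed <- which(!is.na(labels) & labels != 0L)
        seeds <- union(seeds, setdiff(neighbours[[q]], claimed))
      }
    }
  }
  labels
}

#' Reduce significant terms by semantic-similarity clustering
#'
#' Computes pairwise Wang similarities between the significant terms,
#' embeds the 1 - similarity distances in two dimensions (classical metric
#' scaling; deterministic), segments the embedding by density-based
#' clustering (DBSCAN, default epsilon 0.6 and 5 minimum neighbours), and
#' selects per cluster the term with the highest -log10 adjusted p as its
#' representative (ties broken by the smaller term id). Noise points carry
#' cluster -1 and are their own representatives. With fewer significant
#' terms than `min_neighbors`, all terms are noise.
#'
#' @param results an [enrich()] result.
#' @param dag an [ontology()] object.
#' @param epsilon DBSCAN neighbourhood radius in embedded space.
#' @param min_neighbors DBSCAN minimum neighbourhood size.
#' @param seed seed (the default embedding is deterministic; the seed is
#'   applied for interchangeability with stochastic embedders).
#' @return data.frame: term_id, x, y, cluster (-1 = noise), representative.
#' @export
reduce_terms <- function(results, dag, epsilon = 0.6, min_neighbors = 5L,
                         seed = 1L) {
  stopifnot(inherits(dag, "ontology"))
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(term_id = character(0), x = numeric(0), y = numeric(0),
                      cluster = integer(0), representative = logical(0)))
  }
  terms <- sig$term_id
  if (length(terms) == 1L) {
    coords <- matrix(0, 1, 2)
  } else {
    S <- wang_similarity_matrix(dag, terms)
    set.seed(seed)
    coords <- stats::cmdscale(stats::as.dist(1 - S), k = min(2L, length(terms) - 1L))
    if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  }
  rownames(coords) <- terms
  labels <- if (length(terms) < min_neighbors) {
    rep(0L, length(terms))
  } else {
    .dbscan(coords, eps = epsilon, min_pts = min_neighbors)
  }
  cluster <- ifelse(labels == 0L, -1L, labels)
  representative <- logical(length(terms))
  score <- sig$neg_log10_padj
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    if (cl == -1L) {
      representative[idx] <- TRUE      # each noise term stands for itself
    } else {
      best <- idx[order(-score[idx], terms[idx])][1]
      representative[best] <- TRUE
    }
  }
  out <- data.frame(term_id = terms, x = coords[, 1], y = coords[, 2],
                    cluster = cluster, representative = representative,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "epsilon") <- epsilon
  attr(out, "min_neighbors") <- min_neighbors
  out
}
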