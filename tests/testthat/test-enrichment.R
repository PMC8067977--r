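test_that("ontology construction validates edges and rejects cycles", {
  terms <- data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
                      namespace = "bp")
  edges <- data.frame(child = c("a", "b"), parent = c("b", "c"),
                      type = "is_a")
  expect_s3_class(ontology(terms, edges), "ontology")
  cyc <- data.frame(child = c("a", "b", "c"), parent = c("b", "c", "a"),
                    type = "is_a")
  expect_error(ontology(terms, cyc), "cycle")
})

test_that("OBO subset files round-trip", {
  dag <- make_two_family_dag(depth = 3, n_leaves = 4)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- read_obo(path)
  expect_setequal(back$terms$id, dag$terms$id)
  e1 <- dag$edges[order(dag$edges$child, dag$edges$parent), ]
  e2 <- back$edges[order(back$edges$child, back$edges$parent), ]
  expect_equal(e1$parent, e2$parent)
  expect_equal(e1$type, e2$type)
})

test_that("annotation propagation equals a BFS reachability oracle", {
  dag <- make_two_family_dag(depth = 5, n_leaves = 6)
  leaf <- "T:LA001"
  ann <- data.frame(gene_id = "g1", term_id = leaf)
  prop <- propagate_annotations(dag, ann)
  expect_true("T:ROOT" %in% prop$term_id)       # leaf reaches the root
  expect_equal(propagate_annotations(dag, prop), prop)  # idempotent

  # random DAG: closure equals breadth-first reachability
  set.seed(1)
  ids <- sprintf("t%02d", 1:15)
  terms <- data.frame(id = ids, name = ids, namespace = "bp")
  edges <- do.call(rbind, lapply(2:15, function(i) {
    parents <- sample(ids[seq_len(i - 1)], sample(seq_len(min(2, i - 1)), 1))
    data.frame(child = ids[i], parent = parents,
               type = sample(c("is_a", "part_of"), length(parents),
                             replace = TRUE))
  }))
  dag2 <- ontology(terms, edges)
  bfs <- function(start) {
    seen <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(edges$parent[edges$child %in% frontier], seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  }
  for (t in sample(ids, 5)) {
    ann2 <- data.frame(gene_id = "g", term_id = t)
    prop2 <- propagate_annotations(dag2, ann2)
    expect_setequal(prop2$term_id, bfs(t))
  }
  expect_error(propagate_annotations(dag2, data.frame(gene_id = "g",
                                                      term_id = "nope")),
               "unknown")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # N = 20, K = 5, n = 4, k = 3: p = 155/4845
  bg <- sprintf("g%02d", 1:20)
  term_genes <- bg[1:5]
  module <- c(bg[1:3], bg[20])
  ann <- rbind(data.frame(gene_id = term_genes, term_id = "T1"),
               data.frame(gene_id = bg, term_id = "ROOT"))
  res <- enrich(module, bg, ann, min_size = 2, max_size = 20)
  expect_equal(res$p[res$term_id == "T1"],
               (choose(5, 3) * choose(15, 1) + choose(5, 4)) / choose(20, 4),
               tolerance = 1e-12)
  # the all-background term has k = n and p = 1... (always enriched trivially)
  expect_equal(res$k[res$term_id == "ROOT"], 4L)

  # k = 0 gives p = 1
  res0 <- enrich(bg[6:9], bg, ann[ann$term_id == "T1", , drop = FALSE],
                 min_size = 2, max_size = 20)
  expect_equal(res0$p[res0$term_id == "T1"], 1)

  # term outside the size window is not tested
  res14 <- enrich(module, bg, ann, min_size = 6, max_size = 20)
  expect_false("T1" %in% res14$term_id)
  expect_error(enrich(character(0), bg, ann), "empty")
  expect_error(enrich("zzz", bg, ann), "subset")
})

test_that("hypergeometric p agrees with Monte-Carlo resampling", {
  set.seed(2)
  N <- 60; K <- 18; n <- 12
  bg <- sprintf("g%02d", 1:N)
  term_genes <- bg[1:K]
  module <- sample(bg, n)
  k_obs <- sum(module %in% term_genes)
  p <- phyper(k_obs - 1, K, N - K, n, lower.tail = FALSE)
  draws <- replicate(20000, sum(sample(bg, n) %in% term_genes) >= k_obs)
  se <- sqrt(p * (1 - p) / length(draws))
  expect_lt(abs(mean(draws) - p), 3 * se + 1e-12)
})

test_that("Wang similarity matches hand values and a recursive oracle", {
  terms <- data.frame(id = c("B", "A"), name = c("b", "a"), namespace = "bp")
  dag <- ontology(terms, data.frame(child = "A", parent = "B", type = "is_a"))
  expect_equal(wang_similarity(dag, "A", "A"), 1)
  expect_equal(wang_similarity(dag, "A", "B"), 9 / 14, tolerance = 1e-12)

  # random 30-term DAG vs memoized recursive S-value oracle
  set.seed(3)
  ids <- sprintf("w%02d", 1:30)
  tms <- data.frame(id = ids, name = ids, namespace = "bp")
  edges <- do.call(rbind, lapply(2:30, function(i) {
    parents <- sample(ids[seq_len(i - 1)], sample(seq_len(min(2, i - 1)), 1))
    data.frame(child = ids[i], parent = parents,
               type = sample(c("is_a", "part_of"), length(parents),
                             replace = TRUE))
  }))
  dagr <- ontology(tms, edges)
  sv_oracle <- function(term) {
    anc <- c(term, character(0))
    frontier <- term
    repeat {
      nxt <- setdiff(edges$parent[edges$child %in% frontier], anc)
      if (!length(nxt)) break
      anc <- c(anc, nxt); frontier <- nxt
    }
    memo <- new.env()
    sv <- function(t) {
      if (t == term) return(1)
      if (!is.null(memo[[t]])) return(memo[[t]])
      kids <- edges[edges$parent == t & edges$child %in% anc, ]
      val <- max(mapply(function(c, ty) {
        ifelse(ty == "is_a", 0.8, 0.6) * sv(c)
      }, kids$child, kids$type))
      memo[[t]] <- val
      val
    }
    setNames(vapply(anc, sv, numeric(1)), anc)
  }
  sim_oracle <- function(a, b) {
    sa <- sv_oracle(a); sb <- sv_oracle(b)
    common <- intersect(names(sa), names(sb))
    sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
  }
  prs <- combn(sample(ids, 8), 2)
  for (i in seq_len(ncol(prs))) {
    s <- wang_similarity(dagr, prs[1, i], prs[2, i])
    expect_equal(s, sim_oracle(prs[1, i], prs[2, i]), tolerance = 1e-12)
    expect_equal(s, wang_similarity(dagr, prs[2, i], prs[1, i]),
                 tolerance = 1e-12)
    expect_lt(s, 1)                    # distinct terms never reach 1
  }
})

test_that("term reduction separates two semantic families", {
  dag <- make_two_family_dag(depth = 7, n_leaves = 8)
  terms <- c(sprintf("T:LA%03d", 1:8), sprintf("T:LB%03d", 1:8))
  results <- data.frame(term_id = terms,
                        p_adj = rep(c(0.001, 0.01), each = 8),
                        neg_log10_padj = rep(c(3, 2), each = 8) +
                          seq_along(terms) * 1e-3,
                        significant = TRUE)
  cl <- reduce_terms(results, dag, epsilon = 0.6, min_neighbors = 5, seed = 1)
  expect_equal(length(unique(cl$cluster[cl$cluster != -1])), 2L)
  fam <- substr(cl$term_id, 3, 4)
  expect_equal(length(unique(cl$cluster[fam == "LA"])), 1L)
  expect_equal(length(unique(cl$cluster[fam == "LB"])), 1L)
  expect_equal(sum(cl$representative), 2L)
  # representative carries the cluster's maximal score
  for (cc in unique(cl$cluster)) {
    idx <- cl$cluster == cc
    rep_score <- results$neg_log10_padj[match(
      cl$term_id[idx & cl$representative], results$term_id)]
    expect_true(all(results$neg_log10_padj[match(cl$term_id[idx],
                                                 results$term_id)] <=
                      rep_score + 1e-12))
  }

  # cluster structure is invariant to input order
  cl2 <- reduce_terms(results[rev(seq_len(nrow(results))), ], dag,
                      epsilon = 0.6, min_neighbors = 5, seed = 1)
  expect_equal(length(unique(cl2$cluster[cl2$cluster != -1])), 2L)
})

test_that("few significant terms are all noise, each their own representative", {
  dag <- make_two_family_dag(depth = 3, n_leaves = 4)
  results <- data.frame(term_id = c("T:LA001", "T:LA002", "T:LB001"),
                        p_adj = c(0.01, 0.02, 0.03),
                        neg_log10_padj = c(2, 1.7, 1.5),
                        significant = TRUE)
  cl <- reduce_terms(results, dag, min_neighbors = 5)
  expect_true(all(cl$cluster == -1))
  expect_true(all(cl$representative))
})
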