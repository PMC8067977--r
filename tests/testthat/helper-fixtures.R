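# shared fixtures built in code

# balanced 2x2 annotation: n_subjects donors, all four fractions present
make_annotation <- function(n_subjects = 8) {
  tags <- c("NECneg", "NECpos", "TECneg", "TECpos")
  ann <- expand.grid(subject = seq_len(n_subjects), tag = tags,
                     stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("S%02d_%s", ann$subject, ann$tag),
    subject_id = sprintf("P%02d", ann$subject),
    origin = factor(ifelse(grepl("TEC", ann$tag), "tumour", "non_tumour"),
                    levels = c("non_tumour", "tumour")),
    activation = factor(ifelse(grepl("pos", ann$tag), "ENGpos", "ENGneg"),
                        levels = c("ENGneg", "ENGpos")),
    stringsAsFactors = FALSE
  )
}

# block-structured expression: two perfectly coherent modules + noise genes
make_block_matrix <- function(n_per_block = 50, n_noise = 0, n_samples = 20,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  e1 <- rnorm(n_samples)
  e2 <- rnorm(n_samples)
  X <- rbind(
    matrix(rep(e1, each = n_per_block), n_per_block, n_samples) +
      matrix(rnorm(n_per_block * n_samples, 0, noise_sd), n_per_block),
    matrix(rep(e2, each = n_per_block), n_per_block, n_samples) +
      matrix(rnorm(n_per_block * n_samples, 0, noise_sd), n_per_block)
  )
  if (n_noise > 0) {
    X <- rbind(X, matrix(rnorm(n_noise * n_samples), n_noise, n_samples))
  }
  rownames(X) <- sprintf("g%04d", seq_len(nrow(X)))
  colnames(X) <- sprintf("s%02d", seq_len(n_samples))
  X
}

# a deep two-family ontology: two long is_a chains from the root, each
# ending in a parent with `n_leaves` leaf children
make_two_family_dag <- function(depth = 7, n_leaves = 8) {
  ids <- function(prefix, n) sprintf("T:%s%03d", prefix, seq_len(n))
  root <- "T:ROOT"
  chainA <- ids("A", depth); chainB <- ids("B", depth)
  leavesA <- ids("LA", n_leaves); leavesB <- ids("LB", n_leaves)
  all_ids <- c(root, chainA, chainB, leavesA, leavesB)
  terms <- data.frame(id = all_ids, name = all_ids,
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(child = chainA, parent = c(root, chainA[-depth]), type = "is_a"),
    data.frame(child = chainB, parent = c(root, chainB[-depth]), type = "is_a"),
    data.frame(child = leavesA, parent = chainA[depth], type = "is_a"),
    data.frame(child = leavesB, parent = chainB[depth], type = "is_a")
  )
  ontology(terms, edges)
}

# independent step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
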