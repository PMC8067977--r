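#' Simulation configuration for the paired endothelial study design
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_expression()] and [simulate_genesets_and_ontology()]. The
#' defaults emulate the structure of the motivating cohort: 16 subjects, each
#' contributing up to four cell fractions (origin x activation), with
#' per-fraction array dropout chosen so that the expected group sizes are
#' (15, 8, 14, 6) used arrays -- 43 in total. Expression is generated as a
#' low/high two-Gaussian background plus planted co-expression modules whose
#' eigengenes carry origin and/or activation effects and subject-specific
#' random intercepts, mirroring the mixed model fitted downstream.
#'
#' @param n_subjects number of subjects (paired donors).
#' @param fraction_missing probability that a (subject, fraction) array is
#'   missing; scalar or length-4 vector in the order non-tumour/ENG-,
#'   non-tumour/ENG+, tumour/ENG-, tumour/ENG+.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of length `n_modules`.
#' @param origin_effects,activation_effects per-module fixed effects (log2
#'   units) carried by the module eigengene for the tumour and ENG+ levels.
#' @param subject_sd SD of the per-module subject random intercept.
#' @param module_sd SD of the module-specific latent factor in the
#'   eigengene; this is the module-intrinsic co-regulation signal that the
#'   trait effects ride on, and what keeps modules with similar trait
#'   effects distinguishable.
#' @param noise_sd SD of the eigengene-level and gene-level residual noise.
#' @param loading_range interval in (0, 1] from which per-gene loadings on
#'   the module eigengene are drawn uniformly.
#' @param background_low_mean,background_high_mean,background_sd parameters
#'   (log2 units) of the low (unexpressed) and high (expressed) Gaussian
#'   components of the expression background.
#' @param n_background_genes number of background genes drawn from the low
#'   Gaussian.
#' @param n_outlier_samples number of samples whose profiles are replaced by
#'   independent noise (destroying inter-sample correlation, the signal the
#'   zK diagnostic detects).
#' @param seed integer; one global seed drives all randomness, with
#'   per-stage streams derived deterministically from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16,
                       fraction_missing = c(1, 8, 2, 10) / 16,
                       n_modules = 6,
                       module_sizes = c(120, 100, 90, 80, 60, 50),
                       origin_effects = c(2, 1.5, -1.5, 0, 0, 0),
                       activation_effects = c(0, 0, 0, 2, 1.5, -1.5),
                       subject_sd = 0.3,
                       module_sd = 1,
                       noise_sd = 0.3,
                       loading_range = c(0.8, 1),
                       background_low_mean = 4,
                       background_high_mean = 8,
                       background_sd = 1,
                       n_background_genes = 1500,
                       n_outlier_samples = 2,
                       seed = 1L) {
  if (length(fraction_missing) == 1L) fraction_missing <- rep(fraction_missing, 4L)
  stopifnot(
    n_subjects >= 2,
    length(fraction_missing) == 4L,
    all(fraction_missing >= 0 & fraction_missing < 1),
    n_modules == length(module_sizes),
    n_modules == length(origin_effects),
    n_modules == length(activation_effects),
    subject_sd >= 0, module_sd >= 0, noise_sd >= 0, background_sd >= 0,
    length(loading_range) == 2L,
    loading_range[1] > 0, loading_range[2] <= 1,
    loading_range[1] <= loading_range[2],
    n_background_genes >= 0, n_outlier_samples >= 0
  )
  structure(list(
    n_subjects = as.integer(n_subjects),
    fraction_missing = fraction_missing,
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    origin_effects = origin_effects,
    activation_effects = activation_effects,
    subject_sd = subject_sd,
    module_sd = module_sd,
    noise_sd = noise_sd,
    loading_range = loading_range,
    background_low_mean = background_low_mean,
    background_high_mean = background_high_mean,
    background_sd = background_sd,
    n_background_genes = as.integer(n_background_genes),
    n_outlier_samples = as.integer(n_outlier_samples),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# derive a deterministic sub-stream seed from the global seed; kept < 2^31
.derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + as.integer(stage) * 9973L) %% 2147483647L
}

#' Simulate a paired 2x2 cohort with per-fraction array dropout
#'
#' Each subject contributes up to four samples from the crossing of cell
#' origin (non-tumour / tumour) and angiogenic activation (ENG- / ENG+);
#' missingness is applied independently per (subject, fraction).
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` (sample annotation) with columns `sample_id`,
#'   `subject_id`, `origin` (factor: non_tumour, tumour) and `activation`
#'   (factor: ENGneg, ENGpos).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 1L))
  fractions <- data.frame(
    origin = c("non_tumour", "non_tumour", "tumour", "tumour"),
    activation = c("ENGneg", "ENGpos", "ENGneg", "ENGpos"),
    tag = c("NECneg", "NECpos", "TECneg", "TECpos"),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    keep <- stats::runif(4L) >= config$fraction_missing
    for (f in which(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("S%02d_%s", s, fractions$tag[f]),
        subject_id = sprintf("P%02d", s),
        origin = fractions$origin[f],
        activation = fractions$activation[f],
        stringsAsFactors = FALSE
      )
    }
  }
  ann <- do.call(rbind, rows)
  ann$origin <- factor(ann$origin, levels = c("non_tumour", "tumour"))
  ann$activation <- factor(ann$activation, levels = c("ENGneg", "ENGpos"))
  counts <- table(ann$origin, ann$activation)
  if (any(counts == 0)) {
    stop("missingness removed an entire origin x activation group; ",
         "lower fraction_missing or increase n_subjects")
  }
  rownames(ann) <- ann$sample_id
  ann
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Per module m the eigengene is
#' `e_m = beta1_m * origin + beta2_m * activation + subject intercept +
#' module factor + noise` (the module factor is the module-intrinsic latent
#' signal, see [sim_config()]);
#' each module gene is a high-Gaussian baseline plus `loading * e_m` plus
#' residual noise. Background genes are drawn i.i.d. from the low-expression
#' Gaussian. Outlier samples (if requested) have their whole profile replaced
#' by independent noise at the global expression level, which destroys
#' their correlation with every other sample.
#'
#' @param config a [sim_config()] object.
#' @param annotation sample annotation from [simulate_cohort()].
#' @return a list with elements `expr` (genes x samples log2 matrix) and
#'   `truth` (list: `true_module_of_gene`, `true_eigengene_matrix`,
#'   `planted_effects`, `outlier_sample_ids`).
#' @export
simulate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("sample_id", "subject_id", "origin", "activation")
  if (!all(req %in% names(annotation))) {
    stop("annotation must have columns ", paste(req, collapse = ", "))
  }
  set.seed(.derive_seed(config$seed, 2L))
  n_samp <- nrow(annotation)
  subjects <- unique(annotation$subject_id)
  origin01 <- as.numeric(annotation$origin == "tumour")
  activ01 <- as.numeric(annotation$activation == "ENGpos")

  n_mod_genes <- sum(config$module_sizes)
  n_genes <- n_mod_genes + config$n_background_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  module_labels <- sprintf("M%d", seq_len(config$n_modules))
  true_module <- c(rep(module_labels, times = config$module_sizes),
                   rep("unassigned", config$n_background_genes))
  names(true_module) <- gene_ids

  X <- matrix(0, n_genes, n_samp, dimnames = list(gene_ids, annotation$sample_id))
  E <- matrix(0, config$n_modules, n_samp,
              dimnames = list(module_labels, annotation$sample_id))
  row0 <- 0L
  for (m in seq_len(config$n_modules)) {
    b_subj <- stats::rnorm(length(subjects), 0, config$subject_sd)
    names(b_subj) <- subjects
    e <- config$origin_effects[m] * origin01 +
      config$activation_effects[m] * activ01 +
      b_subj[annotation$subject_id] +
      stats::rnorm(n_samp, 0, config$module_sd) +
      stats::rnorm(n_samp, 0, config$noise_sd)
    E[m, ] <- e
    sz <- config$module_sizes[m]
    baseline <- stats::rnorm(sz, config$background_high_mean, config$background_sd)
    loading <- stats::runif(sz, config$loading_range[1], config$loading_range[2])
    X[row0 + seq_len(sz), ] <- baseline + outer(loading, e) +
      matrix(stats::rnorm(sz * n_samp, 0, config$noise_sd), sz, n_samp)
    row0 <- row0 + sz
  }
  if (config$n_background_genes > 0) {
    X[n_mod_genes + seq_len(config$n_background_genes), ] <-
      matrix(stats::rnorm(config$n_background_genes * n_samp,
                          config$background_low_mean, config$background_sd),
             config$n_background_genes, n_samp)
  }

  outlier_ids <- character(0)
  if (config$n_outlier_samples > 0) {
    if (config$n_outlier_samples >= n_samp) stop("more outliers than samples")
    outlier_ids <- sort(sample(annotation$sample_id, config$n_outlier_samples))
    # i.i.d. noise at the global level: shares neither the per-gene
    # baselines nor the low/high class pattern, so the sample loses all
    # correlation with the rest of the cohort (what zK detects)
    mu_glob <- mean(X[, setdiff(colnames(X), outlier_ids)])
    sd_glob <- stats::sd(X[, setdiff(colnames(X), outlier_ids)])
    for (sid in outlier_ids) {
      X[, sid] <- stats::rnorm(n_genes, mu_glob, sd_glob)
    }
  }

  planted <- data.frame(module = module_labels,
                        origin_effect = config$origin_effects,
                        activation_effect = config$activation_effects,
                        stringsAsFactors = FALSE)
  list(expr = X,
       truth = list(true_module_of_gene = true_module,
                    true_eigengene_matrix = E,
                    planted_effects = planted,
                    outlier_sample_ids = outlier_ids))
}

#' Simulate gene sets and a toy ontology matched to the planted modules
#'
#' Produces one gene set per planted module (plus decoy sets of random
#' genes), and a small GO-like DAG (one root, ~10 internal terms, ~30 leaf
#' terms, `is_a` and `part_of` edges) whose leaf annotations are enriched in
#' the planted modules: each module's genes are annotated to a dedicated
#' leaf term, the remaining leaves receive random annotations.
#'
#' @param config a [sim_config()] object.
#' @param truth the `truth` element returned by [simulate_expression()].
#' @param n_decoy_sets number of decoy gene sets of random genes.
#' @param decoy_size size of each decoy set.
#' @return a list: `genesets` (named list of gene-id vectors), `ontology`
#'   (an [ontology()] object), `annotations` (data.frame gene_id, term_id;
#'   direct, not propagated).
#' @export
simulate_genesets_and_ontology <- function(config, truth,
                                           n_decoy_sets = 5, decoy_size = 50) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 3L))
  genes <- names(truth$true_module_of_gene)
  modules <- rownames(truth$true_eigengene_matrix)

  genesets <- lapply(modules, function(m) {
    genes[truth$true_module_of_gene == m]
  })
  names(genesets) <- paste0("SET_", modules)
  for (d in seq_len(n_decoy_sets)) {
    genesets[[sprintf("DECOY_%02d", d)]] <-
      sort(sample(genes, min(decoy_size, length(genes))))
  }

  n_internal <- 10L
  n_leaves <- max(30L, length(modules))
  ids <- sprintf("T:%07d", seq_len(1L + n_internal + n_leaves))
  root <- ids[1]
  internal <- ids[1L + seq_len(n_internal)]
  leaves <- ids[1L + n_internal + seq_len(n_leaves)]
  terms <- data.frame(
    id = ids,
    name = c("biological process root",
             sprintf("internal process %02d", seq_len(n_internal)),
             sprintf("leaf process %02d", seq_len(n_leaves))),
    namespace = "biological_process",
    stringsAsFactors = FALSE
  )
  # internal terms attach to the root, leaves to a cycled internal parent;
  # every third edge is part_of, the rest is_a
  edge_child <- c(internal, leaves)
  edge_parent <- c(rep(root, n_internal),
                   internal[(seq_len(n_leaves) - 1L) %% n_internal + 1L])
  edge_type <- ifelse(seq_along(edge_child) %% 3L == 0L, "part_of", "is_a")
  dag <- ontology(terms, data.frame(child = edge_child, parent = edge_parent,
                                    type = edge_type, stringsAsFactors = FALSE))

  ann <- list()
  for (i in seq_along(modules)) {
    ann[[i]] <- data.frame(gene_id = genesets[[paste0("SET_", modules[i])]],
                           term_id = leaves[i], stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_leaves)[-seq_along(modules)]) {
    sz <- sample(20:60, 1L)
    ann[[j]] <- data.frame(gene_id = sample(genes, min(sz, length(genes))),
                           term_id = leaves[j], stringsAsFactors = FALSE)
  }
  annotations <- unique(do.call(rbind, ann))
  rownames(annotations) <- NULL
  list(genesets = genesets, ontology = dag, annotations = annotations)
}
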