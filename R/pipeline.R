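#' Read / write an expression matrix TSV
#'
#' Rows are genes, columns samples; the first column holds the gene id.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param X genes x samples matrix.
#' @export
write_expression_tsv <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation TSV
#'
#' Columns: sample_id, subject_id, origin (non_tumour/tumour), activation
#' (ENGneg/ENGpos).
#'
#' @param path TSV file.
#' @return annotation data.frame with factor-coded origin and activation.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "subject_id", "origin", "activation") %in% names(ann)))
  ann$origin <- factor(ann$origin, levels = c("non_tumour", "tumour"))
  ann$activation <- factor(ann$activation, levels = c("ENGneg", "ENGpos"))
  rownames(ann) <- ann$sample_id
  ann
}

#' @rdname read_annotation_tsv
#' @param annotation annotation data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# generic deterministic TSV writer for result tables
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks and toggles for [run_pipeline()].
#' Any block can be a list of overrides; stages default to enabled.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global seed.
#' @param simulate list: enabled flag plus [sim_config()] arguments; when
#'   disabled, `expr_file` and `annotation_file` must point to inputs.
#' @param preprocess list: enabled, zk_threshold, two_sided.
#' @param diffexpr list: enabled, contrasts (names), lfc_threshold, alpha.
#' @param gsva list: enabled, tau, gmt_file (optional; simulated sets are
#'   used otherwise).
#' @param coexnet list: enabled plus [network_config()] arguments.
#' @param association list: enabled, hub_fraction, drug_table_file.
#' @param enrichment list: enabled, min_size, max_size, epsilon,
#'   min_neighbors, obo_file, annotation_file.
#' @param expr_file,annotation_file input paths when simulation is off.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            simulate = list(), preprocess = list(),
                            diffexpr = list(), gsva = list(),
                            coexnet = list(), association = list(),
                            enrichment = list(),
                            expr_file = NULL, annotation_file = NULL) {
  dflt <- function(block, defaults) {
    defaults[names(block)] <- block
    defaults
  }
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    expr_file = expr_file, annotation_file = annotation_file,
    simulate = dflt(simulate, list(enabled = TRUE)),
    preprocess = dflt(preprocess, list(enabled = TRUE, zk_threshold = 1.96,
                                       two_sided = FALSE)),
    diffexpr = dflt(diffexpr, list(enabled = TRUE, lfc_threshold = 2,
                                   alpha = 0.05)),
    gsva = dflt(gsva, list(enabled = TRUE, tau = 1, gmt_file = NULL)),
    coexnet = dflt(coexnet, list(enabled = TRUE)),
    association = dflt(association, list(enabled = TRUE, hub_fraction = 0.1,
                                         drug_table_file = NULL)),
    enrichment = dflt(enrichment, list(enabled = TRUE, min_size = 15L,
                                       max_size = 500L, epsilon = 0.6,
                                       min_neighbors = 5L, obo_file = NULL,
                                       annotation_file = NULL))
  )
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full co-expression analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> diffexpr -> gsva ->
#' coexnet -> association -> enrichment, persisting every intermediate as
#' TSV/JSON under the configured output directory, together with a
#' machine-readable run manifest (package version, parameters, input
#' hashes, per-stage gene and sample counts). Stages whose inputs are
#' missing because an upstream stage was disabled raise an error naming the
#' dependency; identical config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()] object.
#' @return (invisibly) the output directory; side effect: artifact files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "tecnet",
                   version = as.character(utils::packageVersion("tecnet")),
                   seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message("[", name, "] ", paste(names(list(...)), unlist(list(...)),
                                   sep = "=", collapse = " "))
  }

  genesets <- NULL; go <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sim_args <- config$simulate[setdiff(names(config$simulate), "enabled")]
    sim_args$seed <- config$seed
    sc <- do.call(sim_config, sim_args)
    annotation <- simulate_cohort(sc)
    sim <- simulate_expression(sc, annotation)
    X <- sim$expr
    gsets <- simulate_genesets_and_ontology(sc, sim$truth)
    genesets <- gsets$genesets
    go <- gsets
    write_expression_tsv(X, file.path(out, "expression.tsv"))
    write_annotation_tsv(annotation, file.path(out, "annotation.tsv"))
    write_gmt(genesets, file.path(out, "genesets.gmt"))
    write_obo(gsets$ontology, file.path(out, "ontology.obo"))
    .write_tsv(gsets$annotations, file.path(out, "gene2term.tsv"))
    jsonlite::write_json(sim$truth[c("true_module_of_gene", "planted_effects",
                                     "outlier_sample_ids")],
                         file.path(out, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    log_stage("simulate", genes = nrow(X), samples = ncol(X),
              outliers = length(sim$truth$outlier_sample_ids))
  } else {
    if (is.null(config$expr_file) || is.null(config$annotation_file)) {
      stop("simulate disabled: expr_file and annotation_file are required")
    }
    X <- read_expression_tsv(config$expr_file)
    annotation <- read_annotation_tsv(config$annotation_file)
    manifest$input_hashes <- as.list(tools::md5sum(c(config$expr_file,
                                                     config$annotation_file)))
    log_stage("load", genes = nrow(X), samples = ncol(X))
  }

  # ---- preprocess: two-Gaussian filter + zK outliers -----------------------
  if (!isTRUE(config$preprocess$enabled)) {
    stop("the preprocess stage is required by all downstream stages")
  }
  fit2g <- fit_two_gaussian(as.numeric(X), seed = config$seed)
  Xf <- filter_low_expression(X, fit2g)
  rep_out <- sample_outliers(Xf, zk_threshold = config$preprocess$zk_threshold,
                             two_sided = config$preprocess$two_sided)
  keep <- setdiff(colnames(Xf), rep_out$excluded_samples)
  Xf <- Xf[, keep, drop = FALSE]
  annotation <- annotation[keep, , drop = FALSE]
  jsonlite::write_json(list(mixture = unclass(fit2g),
                            zk = as.list(rep_out$zk),
                            excluded_samples = rep_out$excluded_samples),
                       file.path(out, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_expression_tsv(Xf, file.path(out, "expression_filtered.tsv"))
  write_annotation_tsv(annotation, file.path(out, "annotation_filtered.tsv"))
  log_stage("preprocess", threshold = round(fit2g$threshold, 4),
            genes_retained = nrow(Xf), samples_retained = ncol(Xf),
            samples_excluded = length(rep_out$excluded_samples))

  design <- design_spec(annotation)

  # ---- moderated differential expression -----------------------------------
  if (isTRUE(config$diffexpr$enabled)) {
    rho <- estimate_consensus_correlation(Xf, design)
    fit <- fit_group_means(Xf, design, rho = rho)
    n_de <- integer(0)
    for (ct in names(design$contrasts)) {
      tab <- moderate_and_test(fit, ct,
                               lfc_threshold = config$diffexpr$lfc_threshold,
                               alpha = config$diffexpr$alpha)
      .write_tsv(tab, file.path(out, paste0("dge_", ct, ".tsv")))
      n_de[ct] <- sum(tab$de)
    }
    log_stage("diffexpr", rho = round(rho, 4),
              de_counts = paste(names(n_de), n_de, sep = ":", collapse = ","))
  }

  # ---- single-sample gene-set scores ---------------------------------------
  if (isTRUE(config$gsva$enabled)) {
    sets <- if (!is.null(config$gsva$gmt_file)) {
      read_gmt(config$gsva$gmt_file)
    } else if (!is.null(genesets)) {
      genesets
    } else {
      stop("gsva requires gmt_file when simulation is disabled")
    }
    stats_g <- gene_level_statistics(Xf)
    scores <- score_sets(stats_g, sets, tau = config$gsva$tau)
    .write_tsv(data.frame(set = rownames(scores$scores), scores$scores,
                          check.names = FALSE),
               file.path(out, "gsva_scores.tsv"))
    for (ct in names(design$contrasts)) {
      ptab <- differential_pathways(scores, design, ct)
      .write_tsv(ptab, file.path(out, paste0("gsva_", ct, ".tsv")))
    }
    log_stage("gsva", sets_scored = nrow(scores$scores),
              sets_dropped = length(scores$dropped))
  }

  # ---- co-expression network -----------------------------------------------
  net <- NULL
  if (isTRUE(config$coexnet$enabled)) {
    net_args <- config$coexnet[setdiff(names(config$coexnet), "enabled")]
    ncfg <- do.call(network_config, net_args)
    net <- iterative_wgcna(Xf, ncfg)
    lab <- net$assignment$module_of_gene
    ass_df <- data.frame(gene_id = names(lab), module = unname(lab),
                         stringsAsFactors = FALSE)
    if (!is.null(net$kme)) {
      ass_df$kME <- NA_real_
      idx <- match(ass_df$module, colnames(net$kme))
      has <- !is.na(idx)
      ass_df$kME[has] <- net$kme[cbind(which(has), idx[has])]
    }
    .write_tsv(ass_df, file.path(out, "modules.tsv"))
    if (!is.null(net$eigengenes)) {
      .write_tsv(data.frame(module = rownames(net$eigengenes), net$eigengenes,
                            check.names = FALSE),
                 file.path(out, "eigengenes.tsv"))
    }
    log_stage("coexnet", modules = length(net$assignment$module_sizes),
              unassigned = sum(lab == "UNASSIGNED"),
              iterations = net$n_iterations, converged = net$converged)
  }

  # ---- eigengene-trait association, hubs -----------------------------------
  selection <- NULL
  if (isTRUE(config$association$enabled)) {
    if (is.null(net) || is.null(net$eigengenes)) {
      stop("association requires the coexnet stage (missing dependency)")
    }
    assoc <- fit_eigengene_model(net$eigengenes, annotation)
    .write_tsv(assoc, file.path(out, "module_trait_association.tsv"))
    selection <- select_modules(net$kme, net$assignment)
    .write_tsv(selection, file.path(out, "module_selection.tsv"))
    pairwise <- compare_eigengene_groups(net$eigengenes, annotation)
    .write_tsv(pairwise, file.path(out, "eigengene_group_comparisons.tsv"))
    lab <- net$assignment$module_of_gene
    assigned <- names(lab)[lab != "UNASSIGNED"]
    ncfg <- do.call(network_config,
                    config$coexnet[setdiff(names(config$coexnet), "enabled")])
    A <- signed_adjacency(.cor_rows(Xf[assigned, , drop = FALSE],
                                    method = ncfg$correlation), ncfg$beta)
    hubs <- intramodular_connectivity(A, lab[assigned],
                                      hub_fraction = config$association$hub_fraction)
    .write_tsv(hubs, file.path(out, "hub_genes.tsv"))
    if (!is.null(config$association$drug_table_file)) {
      drug_table <- utils::read.delim(config$association$drug_table_file,
                                      stringsAsFactors = FALSE)
      .write_tsv(annotate_druggability(hubs, drug_table),
                 file.path(out, "hub_druggability.tsv"))
    }
    log_stage("association", modules_tested = nrow(assoc),
              modules_selected = sum(selection$selected),
              hub_genes = sum(hubs$is_hub))
  }

  # ---- GO enrichment + term reduction --------------------------------------
  if (isTRUE(config$enrichment$enabled)) {
    if (is.null(net) || is.null(net$eigengenes)) {
      stop("enrichment requires the coexnet stage (missing dependency)")
    }
    dag <- if (!is.null(config$enrichment$obo_file)) {
      read_obo(config$enrichment$obo_file)
    } else if (!is.null(go)) go$ontology else {
      stop("enrichment requires obo_file when simulation is disabled")
    }
    ann <- if (!is.null(config$enrichment$annotation_file)) {
      utils::read.delim(config$enrichment$annotation_file,
                        stringsAsFactors = FALSE)
    } else go$annotations
    ann_prop <- propagate_annotations(dag, ann)
    background <- rownames(Xf)
    lab <- net$assignment$module_of_gene
    n_sig <- integer(0)
    for (m in names(net$assignment$module_sizes)) {
      genes <- intersect(names(lab)[lab == m], background)
      er <- enrich(genes, background, ann_prop,
                   min_size = config$enrichment$min_size,
                   max_size = config$enrichment$max_size)
      .write_tsv(er, file.path(out, paste0("enrichment_", m, ".tsv")))
      cl <- reduce_terms(er, dag, epsilon = config$enrichment$epsilon,
                         min_neighbors = config$enrichment$min_neighbors,
                         seed = config$seed)
      .write_tsv(cl, file.path(out, paste0("term_clusters_", m, ".tsv")))
      n_sig[m] <- sum(er$significant)
    }
    log_stage("enrichment", terms_significant = paste(names(n_sig), n_sig,
                                                      sep = ":", collapse = ","))
  }

  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
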