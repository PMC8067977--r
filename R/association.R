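#' Mixed-effects eigengene-trait association
#'
#' Fits, per module eigengene, the random-intercept model
#' `y ~ origin + activation + (1 | subject)` by REML, where origin codes
#' tumour vs non-tumour tissue and activation codes ENG+ vs ENG- cells;
#' the subject intercept accounts for the pairing of fractions from the
#' same donor. t-statistics use Satterthwaite-approximated degrees of
#' freedom; p-values are adjusted across modules, separately per trait.
#' Positive t means up-regulation in tumour (origin) or ENG+ (activation)
#' samples.
#'
#' @param E modules x samples eigengene matrix.
#' @param annotation sample annotation (`subject_id`, `origin`,
#'   `activation`), rows matching the columns of `E`.
#' @param adjust p-value adjustment method across modules (default "BH").
#' @param ddf denominator df method: "Satterthwaite" (default) or "normal"
#'   (z approximation).
#' @return data.frame per module: beta1/t1/p1/p1_adj (origin), beta2/t2/p2/
#'   p2_adj (activation), subject_var, residual_var, singular flag.
#' @export
fit_eigengene_model <- function(E, annotation,
                                adjust = c("BH", "hochberg", "holm", "none"),
                                ddf = c("Satterthwaite", "normal")) {
  adjust <- match.arg(adjust)
  ddf <- match.arg(ddf)
  stopifnot(is.matrix(E), ncol(E) == nrow(annotation))
  if (nlevels(droplevels(factor(annotation$origin))) < 2 ||
      nlevels(droplevels(factor(annotation$activation))) < 2) {
    stop("both levels of origin and activation must be present")
  }
  dat0 <- data.frame(origin = as.numeric(annotation$origin == "tumour"),
                     activation = as.numeric(annotation$activation == "ENGpos"),
                     subject = factor(annotation$subject_id))
  res <- lapply(rownames(E), function(m) {
    dat <- dat0
    dat$y <- E[m, ]
    fit_once <- function(d) {
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ origin + activation + (1 | subject), data = d,
                       REML = TRUE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      cs <- if (ddf == "Satterthwaite") {
        stats::coef(summary(fit))
      } else {
        cc <- stats::coef(summary(fit, ddf = "lme4"))
        cbind(cc, "Pr(>|t|)" = 2 * stats::pnorm(-abs(cc[, "t value"])))
      }
      list(fit = fit, cs = cs)
    }
    r <- tryCatch(fit_once(dat), error = function(e) NULL)
    if (is.null(r)) {
      # perfectly fitting (zero-residual) eigengene: floor the residual by a
      # deterministic infinitesimal perturbation and flag the fit
      dat$y <- dat$y + 1e-8 * max(1, stats::sd(dat$y)) *
        sin(seq_len(nrow(dat)))
      r <- fit_once(dat)
      r$floored <- TRUE
    }
    fit <- r$fit
    cs <- r$cs
    vc <- as.data.frame(lme4::VarCorr(fit))
    data.frame(module = m,
               beta1 = cs["origin", "Estimate"],
               se1 = cs["origin", "Std. Error"],
               t1 = cs["origin", "t value"],
               p1 = cs["origin", "Pr(>|t|)"],
               beta2 = cs["activation", "Estimate"],
               se2 = cs["activation", "Std. Error"],
               t2 = cs["activation", "t value"],
               p2 = cs["activation", "Pr(>|t|)"],
               subject_var = vc$vcov[vc$grp == "subject"],
               residual_var = vc$vcov[vc$grp == "Residual"],
               singular = lme4::isSingular(fit) || isTRUE(r$floored),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p1_adj <- stats::p.adjust(out$p1, method = adjust)
  out$p2_adj <- stats::p.adjust(out$p2, method = adjust)
  rownames(out) <- NULL
  out
}

#' Select modules by median module membership
#'
#' A module is retained for downstream interpretation only when the median
#' absolute membership (|kME|) of its genes strictly exceeds the threshold,
#' indicating a stable, well-fitting eigengene.
#'
#' @param kme genes x modules kME matrix.
#' @param assignment gene -> module labels (or `module_assignment`).
#' @param threshold selection threshold (default 0.8, strict >).
#' @return data.frame: module, median_kme, selected.
#' @export
select_modules <- function(kme, assignment, threshold = 0.8) {
  labels <- if (inherits(assignment, "module_assignment")) {
    assignment$module_of_gene
  } else assignment
  mods <- colnames(kme)
  med <- vapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    genes <- intersect(genes, rownames(kme))
    if (!length(genes)) return(NA_real_)
    stats::median(abs(kme[genes, m]))
  }, numeric(1))
  data.frame(module = mods, median_kme = med,
             selected = !is.na(med) & med > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intramodular connectivity and hub-gene calling
#'
#' `kWithin_i` is the sum of gene i's adjacencies to the other genes of its
#' module; `kWithin_norm` divides by the module's maximum. The top 10% of
#' genes per module by normalized connectivity (count = ceiling(0.1 * size),
#' ties broken by gene id) are flagged as hub genes.
#'
#' @param A adjacency matrix over (at least) the assigned genes.
#' @param assignment gene -> module labels (or `module_assignment`).
#' @param hub_fraction fraction of genes flagged per module (default 0.1).
#' @return an object of class `hub_table` (data.frame): gene_id, module,
#'   kWithin, kWithin_norm, is_hub.
#' @export
intramodular_connectivity <- function(A, assignment, hub_fraction = 0.1) {
  labels <- if (inherits(assignment, "module_assignment")) {
    assignment$module_of_gene
  } else assignment
  labels <- labels[labels != "UNASSIGNED"]
  if (!all(names(labels) %in% rownames(A))) {
    stop("adjacency must cover all assigned genes")
  }
  out <- list()
  for (m in sort(unique(labels))) {
    genes <- sort(names(labels)[labels == m])
    if (length(genes) < 2) stop("module ", m, " is a singleton")
    Am <- A[genes, genes, drop = FALSE]
    kw <- rowSums(Am) - diag(Am)
    kwn <- kw / max(kw)
    n_hub <- ceiling(hub_fraction * length(genes))
    ord <- order(-kwn, genes)
    is_hub <- logical(length(genes))
    is_hub[ord[seq_len(n_hub)]] <- TRUE
    out[[m]] <- data.frame(gene_id = genes, module = m, kWithin = kw,
                           kWithin_norm = kwn, is_hub = is_hub,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("hub_table", "data.frame")
  res
}

#' Pairwise group comparisons of module eigengenes
#'
#' Two-sample Student's t-tests between the four origin x activation groups
#' for every eigengene, with p-values adjusted within each module. Pairs
#' where a group has fewer than two samples are reported as NA with a
#' warning.
#'
#' @param E modules x samples eigengene matrix.
#' @param annotation sample annotation matching the columns of `E`.
#' @param adjust adjustment method within module (default "BH").
#' @return data.frame: module, group1, group2, mean_diff, t, p, p_adj.
#' @export
compare_eigengene_groups <- function(E, annotation, adjust = "BH") {
  stopifnot(is.matrix(E), ncol(E) == nrow(annotation))
  grp <- paste0(ifelse(annotation$origin == "tumour", "TEC", "NEC"),
                ifelse(annotation$activation == "ENGpos", "pos", "neg"))
  lv <- intersect(c("NECneg", "NECpos", "TECneg", "TECpos"), unique(grp))
  pairs <- utils::combn(lv, 2)
  out <- list()
  for (m in rownames(E)) {
    rows <- apply(pairs, 2L, function(pr) {
      y1 <- E[m, grp == pr[1]]
      y2 <- E[m, grp == pr[2]]
      if (length(y1) < 2 || length(y2) < 2) {
        warning("degenerate group in ", m, " (", pr[1], " vs ", pr[2],
                "); comparison skipped")
        return(data.frame(module = m, group1 = pr[1], group2 = pr[2],
                          mean_diff = NA_real_, t = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      if (stats::sd(c(y1, y2)) == 0) {
        tt <- list(statistic = 0, p.value = 1)
      } else if (stats::sd(y1) == 0 && stats::sd(y2) == 0) {
        tt <- list(statistic = sign(mean(y1) - mean(y2)) * Inf,
                   p.value = as.numeric(mean(y1) == mean(y2)))
      } else {
        t0 <- stats::t.test(y1, y2, var.equal = TRUE)
        tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
      }
      data.frame(module = m, group1 = pr[1], group2 = pr[2],
                 mean_diff = mean(y1) - mean(y2),
                 t = tt$statistic, p = tt$p.value, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
    out[[m]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate hub genes with drug interactions from a local lookup table
#'
#' Left-joins the hub genes onto a user-supplied gene-drug interaction
#' table (columns `gene_id`, `drug`, optional `evidence`); matching is
#' case-insensitive on the gene symbol. A hub with at least one drug is
#' flagged druggable.
#'
#' @param hubs a [intramodular_connectivity()] result (only `is_hub` rows
#'   are annotated).
#' @param drug_table data.frame with columns `gene_id`, `drug` and
#'   optionally `evidence`.
#' @return data.frame: gene_id, module, kWithin_norm, drug, evidence,
#'   druggable (one row per gene-drug pair; genes without drugs keep one
#'   row with NA drug).
#' @export
annotate_druggability <- function(hubs, drug_table) {
  stopifnot(inherits(hubs, "data.frame"))
  if (!all(c("gene_id", "drug") %in% names(drug_table))) {
    stop("drug_table must have columns gene_id and drug")
  }
  if (!"evidence" %in% names(drug_table)) {
    drug_table[["evidence"]] <- rep(NA_character_, nrow(drug_table))
  }
  h <- hubs[hubs$is_hub, c("gene_id", "module", "kWithin_norm")]
  drug_table$gene_key <- toupper(drug_table$gene_id)
  h$gene_key <- toupper(h$gene_id)
  merged <- merge(h, drug_table[, c("gene_key", "drug", "evidence")],
                  by = "gene_key", all.x = TRUE, sort = FALSE)
  merged$druggable <- !is.na(merged$drug)
  merged <- merged[order(merged$module, merged$gene_id, merged$drug,
                         na.last = TRUE), ]
  rownames(merged) <- NULL
  merged[, c("gene_id", "module", "kWithin_norm", "drug", "evidence", "druggable")]
}
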