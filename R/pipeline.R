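# End-to-end orchestration.  A run either loads the four input tables
# or simulates them, then executes both preprocessing branches
# (unit-variance scaling for PCA; log2 + mean centering for OPLS-DA),
# the pairwise OPLS-DA star design around the reference group, the
# differential / non-differential / top-k / essence screening,
# enrichment of the resulting sets, and one fitted discriminant panel
# per comparison — returning a machine-readable run report and,
# optionally, writing every stage table to disk.

#' Pipeline run configuration
#'
#' Exactly one of the file-path inputs (`abundance`, `metadata`,
#' `annotation`, `pathways`) or `simulate` must be given.
#'
#' @param abundance,metadata,annotation,pathways Input file paths
#'   (abundance/metadata/annotation TSV, pathways GMT).
#' @param simulate A [cohort_config()] to generate the inputs instead.
#' @param reference Reference syndrome common to all comparisons
#'   (default `"IPBS"`, the star design).
#' @param comparisons Optional list of `c(reference, contrast)` pairs;
#'   defaults to the reference versus every other group present, in the
#'   order PST, PQS, PQD.
#' @param top_k Top-abundance set size per group (default 100).
#' @param vip_threshold,log2fc_threshold,symmetric Screening thresholds
#'   (see [call_differential()]).
#' @param n_ortho,cv_folds OPLS-DA settings (see [oplsda()]).
#' @param n_perm Label permutations per comparison; 0 skips the
#'   permutation test.
#' @param enrichment_factor `"query"` (k/n) or `"pathway"` (k/K).
#' @param lambda,discriminant_cv_folds Discriminant settings (see
#'   [fit_discriminant()], [cv_auc()]).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for stage tables and the
#'   JSON report.
#' @return A validated `run_config` list.
#' @export
run_config <- function(abundance = NULL, metadata = NULL,
                       annotation = NULL, pathways = NULL,
                       simulate = NULL,
                       reference = "IPBS", comparisons = NULL,
                       top_k = 100, vip_threshold = 1,
                       log2fc_threshold = 1, symmetric = TRUE,
                       n_ortho = 1, cv_folds = 7, n_perm = 0,
                       enrichment_factor = "query",
                       lambda = 1e-3, discriminant_cv_folds = 5,
                       seed = 1L, out_dir = NULL) {
  paths <- list(abundance = abundance, metadata = metadata,
                annotation = annotation, pathways = pathways)
  have_paths <- !vapply(paths, is.null, TRUE)
  if (!is.null(simulate) && any(have_paths)) {
    stop("give either input paths or a simulate config, not both")
  }
  if (is.null(simulate)) {
    if (!all(have_paths)) {
      stop("all four input paths are required when not simulating: ",
           paste(names(paths)[!have_paths], collapse = ", "))
    }
  } else {
    stopifnot(inherits(simulate, "cohort_config"))
  }
  structure(list(paths = paths, simulate = simulate,
                 reference = reference, comparisons = comparisons,
                 top_k = top_k, vip_threshold = vip_threshold,
                 log2fc_threshold = log2fc_threshold,
                 symmetric = symmetric, n_ortho = n_ortho,
                 cv_folds = cv_folds, n_perm = n_perm,
                 enrichment_factor = enrichment_factor,
                 lambda = lambda,
                 discriminant_cv_folds = discriminant_cv_folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

.config_echo <- function(config) {
  e <- unclass(config)
  e$simulate <- if (is.null(e$simulate)) NULL else
    lapply(unclass(e$simulate), function(v) {
      if (is.list(v)) lapply(v, unclass) else v
    })
  e
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, imputation, both preprocessing branches,
#' PCA (overall and per comparison), pairwise OPLS-DA with optional
#' permutation validation, fold changes and differential /
#' non-differential calls, the top-k abundance core and essence set,
#' enrichment of the essence and differential sets, and a fitted
#' discriminant panel per comparison.  Fully deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` (a nested list; see the
#'   `comparisons`, `screening`, `enrichment` and `discriminant`
#'   elements).  If `config$out_dir` is set, stage tables and
#'   `run_report.json` are written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
  } else {
    cohort <- list(abundance = read_abundance(config$paths$abundance),
                   metadata = read_metadata(config$paths$metadata),
                   annotation = read_annotation(config$paths$annotation),
                   pathways = read_pathway_gmt(config$paths$pathways))
  }
  check_samples_match(cohort$abundance, cohort$metadata)
  labels <- cohort$metadata$syndrome[
    match(rownames(cohort$abundance), cohort$metadata$sample_id)]
  groups_present <- intersect(SYNDROME_LEVELS, unique(labels))
  if (!(config$reference %in% groups_present)) {
    stop("reference group ", config$reference, " absent from metadata")
  }
  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    contrasts <- intersect(c("PST", "PQS", "PQD"),
                           setdiff(groups_present, config$reference))
    comparisons <- lapply(contrasts, function(g) c(config$reference, g))
  }
  for (cmp in comparisons) {
    if (cmp[1] != config$reference) {
      stop("star design violated: comparison ", paste(cmp, collapse = " vs "),
           " does not start at reference ", config$reference)
    }
    if (!(cmp[2] %in% groups_present)) {
      stop("comparison group absent from metadata: ", cmp[2])
    }
  }
  cmp_names <- vapply(comparisons, function(cmp)
    paste(cmp, collapse = "_vs_"), "")

  n_missing <- sum(is.na(cohort$abundance))
  imputed <- impute_half_min(cohort$abundance)
  uv <- uv_scale(imputed)
  lc <- log2_center(imputed)

  pca_overall <- pca(uv, n_components = 2)

  per_comparison <- list()
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    sel <- labels %in% cmp
    sub_labels <- labels[sel]
    sub_pca <- pca(uv_scale(imputed[sel, , drop = FALSE]), n_components = 2)
    fit <- oplsda(lc[sel, , drop = FALSE], sub_labels,
                  n_ortho = config$n_ortho, cv_folds = config$cv_folds,
                  seed = seed + i)
    perm <- if (config$n_perm > 0) {
      permutation_test(lc[sel, , drop = FALSE], sub_labels,
                       n_ortho = config$n_ortho, n_perm = config$n_perm,
                       cv_folds = config$cv_folds, seed = seed + 100 + i)
    } else NULL
    fc <- fold_change(imputed, labels, cmp[1], cmp[2])
    calls <- call_differential(fit$vip, fc,
                               vip_threshold = config$vip_threshold,
                               log2fc_threshold = config$log2fc_threshold,
                               symmetric = config$symmetric)
    table_ <- cbind(calls,
                    weight = unname(fit$weights),
                    loading = unname(fit$loadings),
                    p1 = fit$splot$p1, pcorr = fit$splot$pcorr)
    per_comparison[[cmp_names[i]]] <- list(
      groups = cmp,
      n = stats::setNames(c(sum(labels == cmp[1]), sum(labels == cmp[2])),
                          cmp),
      pca = sub_pca, oplsda = fit, permutation = perm,
      table = table_,
      differential = sort(calls$metabolite_id[calls$status == "differential"], method = "radix"),
      nondifferential = sort(calls$metabolite_id[
        calls$status == "nondifferential"], method = "radix"))
  }

  topk <- top_k_abundant_core(imputed, labels, k = config$top_k)
  ess <- essence_set(lapply(per_comparison, `[[`, "nondifferential"),
                     topk$core, required = cmp_names)

  background <- colnames(imputed)
  enr_essence <- enrich(ess$essence, background, cohort$annotation,
                        cohort$pathways, factor = config$enrichment_factor)
  enr_diff <- lapply(per_comparison, function(pc) {
    enrich(pc$differential, background, cohort$annotation,
           cohort$pathways, factor = config$enrichment_factor)
  })

  disc <- list()
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    nm <- cmp_names[i]
    cand <- per_comparison[[nm]]$differential
    if (!length(cand)) {
      disc[[nm]] <- list(fitted = FALSE,
                         note = "no differential metabolites; panel not fitted")
      next
    }
    sel <- labels %in% cmp
    m <- fit_discriminant(imputed[sel, , drop = FALSE], labels[sel],
                          positive = cmp[2], candidates = cand,
                          lambda = config$lambda)
    cv <- cv_auc(imputed[sel, , drop = FALSE], labels[sel],
                 positive = cmp[2], candidates = cand,
                 lambda = config$lambda,
                 folds = config$discriminant_cv_folds,
                 seed = seed + 200 + i)
    disc[[nm]] <- list(fitted = TRUE, model = m, cv_auc = cv$auc,
                       auc = m$roc$auc,
                       sensitivity = m$roc$sensitivity,
                       specificity = m$roc$specificity,
                       cutoff = m$cutoff)
  }

  report <- structure(list(
    package_version = as.character(utils::packageVersion("syndromet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = .config_echo(config),
    cohort = list(
      n_samples = nrow(cohort$abundance),
      group_sizes = vapply(groups_present, function(g)
        sum(labels == g), 0L),
      n_metabolites = ncol(cohort$abundance),
      n_primary_classes = length(unique(cohort$annotation$primary_class)),
      n_secondary_classes = if ("secondary_class" %in%
                                colnames(cohort$annotation))
        length(unique(cohort$annotation$secondary_class)) else NA_integer_,
      n_missing_cells = n_missing),
    pca = pca_overall,
    comparisons = per_comparison,
    screening = list(top_k = config$top_k,
                     topk_per_group_sizes = lengths(topk$per_group),
                     topk_core = topk$core,
                     nondiff_core = ess$nondiff_core,
                     essence = ess$essence,
                     sizes = c(topk_core = length(topk$core),
                               nondiff_core = length(ess$nondiff_core),
                               essence = length(ess$essence))),
    enrichment = c(list(essence = enr_essence), enr_diff),
    discriminant = disc,
    inputs = cohort),
    class = "run_report")

  if (!is.null(config$out_dir)) .write_run_outputs(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("syndromet run (seed", x$seed, ")\n")
  cat("  cohort:", x$cohort$n_samples, "samples x",
      x$cohort$n_metabolites, "metabolites (",
      paste(names(x$cohort$group_sizes), x$cohort$group_sizes,
            collapse = ", "), ")\n")
  for (nm in names(x$comparisons)) {
    pc <- x$comparisons[[nm]]
    cat(sprintf("  %s: %d differential, %d non-differential (R2Y %.2f, Q2 %.2f)\n",
                nm, length(pc$differential), length(pc$nondifferential),
                pc$oplsda$r2y, pc$oplsda$q2))
  }
  s <- x$screening$sizes
  cat(sprintf("  cores: top-%d core %d, non-differential core %d, essence %d\n",
              x$screening$top_k, s["topk_core"], s["nondiff_core"],
              s["essence"]))
  for (nm in names(x$discriminant)) {
    d <- x$discriminant[[nm]]
    if (isTRUE(d$fitted)) {
      cat(sprintf("  panel %s: AUC %.3f (CV %.3f), sens %.3f, spec %.3f\n",
                  nm, d$auc, d$cv_auc, d$sensitivity, d$specificity))
    } else {
      cat("  panel ", nm, ": ", d$note, "\n", sep = "")
    }
  }
  invisible(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
}

.write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # overall PCA scores
  sc <- report$pca$scores
  .write_tsv(data.frame(sample_id = rownames(sc), sc, check.names = FALSE),
             file.path(out_dir, "pca_scores.tsv"))
  for (nm in names(report$comparisons)) {
    pc <- report$comparisons[[nm]]
    .write_tsv(pc$table, file.path(out_dir, paste0(nm, "_metabolites.tsv")))
  }
  for (nm in names(report$enrichment)) {
    .write_tsv(report$enrichment[[nm]],
               file.path(out_dir, paste0("enrichment_", nm, ".tsv")))
  }
  for (nm in names(report$discriminant)) {
    d <- report$discriminant[[nm]]
    if (!isTRUE(d$fitted)) next
    roc <- d$model$roc
    .write_tsv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                          tpr = roc$tpr),
               file.path(out_dir, paste0("roc_", nm, ".tsv")))
  }
  jsonlite::write_json(.report_json(report),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

# Condensed, JSON-friendly view of a run report (no matrices).
.report_json <- function(report) {
  list(
    package_version = report$package_version,
    created = report$created,
    seed = report$seed,
    cohort = report$cohort,
    comparisons = lapply(report$comparisons, function(pc) {
      list(groups = pc$groups, n = as.list(pc$n),
           r2y = pc$oplsda$r2y, q2 = pc$oplsda$q2,
           permutation_p = if (is.null(pc$permutation)) NULL else
             pc$permutation$p_value,
           n_differential = length(pc$differential),
           n_nondifferential = length(pc$nondifferential),
           differential = pc$differential)
    }),
    screening = list(top_k = report$screening$top_k,
                     sizes = as.list(report$screening$sizes),
                     topk_core = report$screening$topk_core,
                     nondiff_core = report$screening$nondiff_core,
                     essence = report$screening$essence),
    enrichment = lapply(report$enrichment, function(df)
      df[, setdiff(colnames(df), "members"), drop = FALSE]),
    discriminant = lapply(report$discriminant, function(d) {
      if (!isTRUE(d$fitted)) return(list(fitted = FALSE, note = d$note))
      list(fitted = TRUE,
           terms = d$model$terms,
           cutoff = d$cutoff, auc = d$auc, cv_auc = d$cv_auc,
           sensitivity = d$sensitivity, specificity = d$specificity)
    }))
}
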