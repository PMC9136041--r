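# Linear metabolite score panels: weighted sums of raw intensities
# (no intercept, matching the shape of published serum panels),
# fitted here by weakly L2-penalized logistic regression with the
# intercept folded into the decision cutoff, and evaluated by ROC
# curve, AUC and the Youden index.

#' Evaluate a linear metabolite score
#'
#' Computes `score = sum(weight_i * intensity_i)` over the model's
#' terms.  No intercept is added.
#'
#' @param model A `discriminant_model` (see [fit_discriminant()],
#'   [reference_panel()]), i.e. a list with a `terms` data.frame of
#'   `metabolite_id` and `weight`.
#' @param newdata Either a named numeric vector (one sample) or a
#'   numeric matrix with metabolite column names (samples in rows).
#'   Every model metabolite must be present.
#' @return Numeric score(s), one per sample.
#' @export
linear_score <- function(model, newdata) {
  terms <- model$terms
  stopifnot(is.data.frame(terms),
            all(c("metabolite_id", "weight") %in% colnames(terms)))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  miss <- setdiff(terms$metabolite_id, colnames(newdata))
  if (length(miss)) {
    stop("sample lacks model metabolite(s): ", paste(miss, collapse = ", "))
  }
  drop(newdata[, terms$metabolite_id, drop = FALSE] %*% terms$weight)
}

# Weakly ridge-penalized logistic regression by iteratively reweighted
# least squares.  Columns are standardized internally (penalty applies
# on the standardized scale, intercept unpenalized); coefficients are
# returned on the raw intensity scale.  The weak penalty keeps the fit
# defined under complete separation.
.ridge_logistic <- function(x, y01, lambda = 1e-3, max_iter = 200,
                            tol = 1e-9) {
  n <- nrow(x)
  p <- ncol(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  xa <- cbind(`(Intercept)` = 1, xs)
  coefs <- rep(0, p + 1)
  pen <- diag(c(0, rep(lambda, p)), p + 1, p + 1)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(xa %*% coefs)
    prob <- 1 / (1 + exp(-eta))
    wts <- pmax(prob * (1 - prob), 1e-10)
    z <- eta + (y01 - prob) / wts
    a <- crossprod(xa * wts, xa) / n + pen
    b <- crossprod(xa * wts, z) / n
    new_coefs <- drop(solve(a, b))
    delta <- max(abs(new_coefs - coefs))
    coefs <- new_coefs
    if (delta < tol * (1 + max(abs(coefs)))) break
  }
  list(weights = coefs[-1] / sdv,
       intercept = coefs[1] - sum(coefs[-1] * mu / sdv),
       iterations = it,
       converged = delta < tol * (1 + max(abs(coefs))))
}

#' Fit a linear discriminant metabolite panel
#'
#' Fits a weakly L2-penalized logistic regression of the class on raw
#' candidate intensities.  The reported model is intercept-free — the
#' logistic intercept is absorbed into the decision `cutoff`, which is
#' placed at the Youden-optimal point of the training ROC curve — so
#' fitted panels have the same shape as the bundled reference panels.
#'
#' @param mat Complete abundance matrix (samples x metabolites, raw
#'   imputed intensities) restricted or restrictable to candidates.
#' @param labels Two-class label vector, each class with >= 5 samples.
#' @param positive Label of the positive class (the concurrent
#'   syndrome); defaults to the alphabetically later label.
#' @param candidates Metabolite ids to use as features (default: all
#'   columns of `mat`).
#' @param lambda Ridge penalty on standardized coefficients (weak,
#'   default 1e-3).
#' @return A `discriminant_model`: `comparison` (negative, positive),
#'   `terms` (metabolite_id, weight per raw-intensity unit), `cutoff`
#'   on the score scale, plus the training `roc` ([roc_curve()]).
#' @export
fit_discriminant <- function(mat, labels, positive = NULL,
                             candidates = colnames(mat), lambda = 1e-3) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "fit a discriminant on")
  enc <- .binary_y(labels, min_per_class = 5L)
  if (is.null(positive)) positive <- enc$groups[2]
  if (!(positive %in% enc$groups)) stop("positive class not in labels: ", positive)
  negative <- setdiff(enc$groups, positive)
  if (!length(candidates)) stop("candidate metabolite set is empty")
  miss <- setdiff(candidates, colnames(mat))
  if (length(miss)) {
    stop("candidate metabolite(s) absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  xm <- mat[, candidates, drop = FALSE]
  y01 <- as.numeric(enc$labels == positive)
  fit <- .ridge_logistic(xm, y01, lambda = lambda)
  scores <- drop(xm %*% fit$weights)
  roc <- roc_curve(scores, enc$labels, positive = positive)
  structure(list(comparison = c(negative, positive),
                 terms = data.frame(metabolite_id = candidates,
                                    weight = unname(fit$weights),
                                    stringsAsFactors = FALSE),
                 cutoff = roc$youden_cutoff,
                 intercept = fit$intercept,
                 roc = roc),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Linear discriminant panel:", x$comparison[1], "vs",
      x$comparison[2], "(positive)\n")
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %+.3g x %s\n", x$terms$weight[i],
                x$terms$metabolite_id[i]))
  }
  if (!is.null(x$cutoff)) cat(sprintf("  cutoff: %.6g\n", x$cutoff))
  if (!is.null(x$roc)) cat(sprintf("  training AUC: %.3f\n", x$roc$auc))
  invisible(x)
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Thresholds are the distinct score values (descending, with an
#' infinite sentinel); a sample is called positive when its score is at
#' or above the threshold.  The AUC is the trapezoidal area, which
#' equals the tie-aware pairwise probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`.  The Youden cutoff
#' maximizes `sensitivity + specificity - 1`; ties are broken toward
#' higher specificity.  Scores are not auto-flipped: an AUC below 0.5
#' is reported as-is, with a warning.
#'
#' @param scores Numeric score per sample.
#' @param labels Two-class label vector.
#' @param positive Label of the positive class (default: alphabetically
#'   later label).
#' @return An object of class `roc_result`: `thresholds`, `fpr`, `tpr`
#'   (per threshold), `auc`, `youden_cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  groups <- sort(unique(labels), method = "radix")
  if (length(groups) != 2) {
    stop("exactly two classes required, got ", paste(groups, collapse = ", "))
  }
  if (is.null(positive)) positive <- groups[2]
  if (!(positive %in% groups)) stop("positive class not in labels: ", positive)
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (auc < 0.5) {
    warning("AUC below 0.5 (", sprintf("%.3f", auc),
            "): the score is oriented against the positive class")
  }
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[order(fpr[best], -thr[best])][1]   # prefer higher specificity
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 youden_cutoff = thr[best],
                 sensitivity = tpr[best],
                 specificity = 1 - fpr[best],
                 positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; Youden cutoff %.6g (sensitivity %.3f, specificity %.3f)\n",
    x$auc, x$youden_cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Cross-validated AUC of a fitted panel
#'
#' Stratified k-fold cross-validation: a panel is refitted on each
#' training split and the held-out samples are scored; the pooled
#' out-of-fold scores give a single ROC/AUC.
#'
#' @inheritParams fit_discriminant
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A list: `auc`, `roc` (pooled [roc_curve()]), `scores`
#'   (out-of-fold score per sample), `folds`.
#' @export
cv_auc <- function(mat, labels, positive = NULL,
                   candidates = colnames(mat), lambda = 1e-3,
                   folds = 5, seed = 1L) {
  enc <- .binary_y(labels, min_per_class = 2L)
  if (is.null(positive)) positive <- enc$groups[2]
  oof <- rep(NA_real_, nrow(mat))
  .with_seed(seed, {
    fold <- .stratified_folds(enc$labels, folds)
    for (f in seq_len(folds)) {
      te <- fold == f
      if (!any(te)) next
      m <- fit_discriminant(mat[!te, , drop = FALSE], enc$labels[!te],
                            positive = positive, candidates = candidates,
                            lambda = lambda)
      oof[te] <- linear_score(m, mat[te, , drop = FALSE])
    }
  })
  roc <- roc_curve(oof, enc$labels, positive = positive)
  list(auc = roc$auc, roc = roc, scores = oof, folds = folds)
}

#' Bundled fixed-coefficient reference panels
#'
#' Three intercept-free serum metabolite panels for discriminating
#' IPBS from each concurrent syndrome (positive class PST, PQS or
#' PQD), with fixed coefficients per raw-intensity unit.  They ship as
#' a JSON file under `inst/extdata/` and are loadable by comparison
#' name.
#'
#' @param name One of `"IPBS_vs_PST"`, `"IPBS_vs_PQS"`,
#'   `"IPBS_vs_PQD"`.
#' @return For `reference_panel()`, a `discriminant_model`; for
#'   `reference_panels()`, a named list of all bundled models.
#' @export
reference_panel <- function(name) {
  panels <- reference_panels()
  if (!(name %in% names(panels))) {
    stop("unknown panel ", dQuote(name), "; available: ",
         paste(names(panels), collapse = ", "))
  }
  panels[[name]]
}

#' @rdname reference_panel
#' @export
reference_panels <- function() {
  path <- system.file("extdata", "reference_panels.json",
                      package = "syndromet", mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  panels <- lapply(raw, function(p) {
    terms <- do.call(rbind, lapply(p$terms, function(t) {
      data.frame(metabolite_id = t$metabolite_id, weight = t$weight,
                 stringsAsFactors = FALSE)
    }))
    structure(list(comparison = unlist(p$comparison), terms = terms,
                   cutoff = p$cutoff, roc = NULL),
              class = "discriminant_model")
  })
  stats::setNames(panels, vapply(raw, `[[`, "", "name"))
}
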