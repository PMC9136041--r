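# Latent-variable models: PCA on unit-variance-scaled intensities and
# two-class OPLS-DA on log2-centered intensities.  The OPLS fit follows
# the classical orthogonal-projection scheme: orthogonal components are
# extracted and deflated from X first, then a single predictive
# component is taken against the class vector.  For a univariate
# response the NIPALS inner loop is closed-form (one pass), so each
# component is exact rather than iterative.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Principal component analysis
#'
#' PCA by singular value decomposition of the column-centered matrix.
#' The caller is expected to pass unit-variance-scaled intensities (see
#' [uv_scale()]); the function itself only centers.
#'
#' @param mat Complete numeric matrix (samples x variables).
#' @param n_components Number of components to return; at most
#'   `min(nrow - 1, ncol)`.
#' @return An object of class `pca_result`: `scores` (samples x
#'   components), `loadings` (variables x components, orthonormal),
#'   `explained_variance` (fraction per returned component), `center`.
#' @export
pca <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "run PCA on")
  kmax <- min(nrow(mat) - 1L, ncol(mat))
  if (n_components < 1 || n_components > kmax) {
    stop("n_components must be in 1..", kmax,
         " (= min(n_samples - 1, n_variables))")
  }
  ctr <- colMeans(mat)
  xc <- sweep(mat, 2, ctr, "-")
  sv <- svd(xc)
  tot <- sum(sv$d^2)
  ev <- if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d))
  k <- n_components
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  cn <- paste0("PC", seq_len(k))
  dimnames(scores) <- list(rownames(mat), cn)
  dimnames(loadings) <- list(colnames(mat), cn)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = stats::setNames(ev[seq_len(k)], cn),
                 center = ctr),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "variables,",
      ncol(x$scores), "components\n")
  cat("explained variance:",
      paste(sprintf("%s %.1f%%", names(x$explained_variance),
                    100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

# Validate a two-class label vector; returns list(groups, y) with the
# class vector encoded -1/+1 (alphabetically later group positive)
# and centered.
.binary_y <- function(labels, min_per_class = 3L) {
  labels <- as.character(labels)
  groups <- sort(unique(labels), method = "radix")
  if (length(groups) != 2) {
    stop("exactly two classes required, got ",
         paste(groups, collapse = ", "))
  }
  counts <- table(labels)
  if (any(counts < min_per_class)) {
    stop("each class needs >= ", min_per_class, " samples (",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  y <- ifelse(labels == groups[2], 1, -1)
  list(groups = groups, y = y - mean(y), labels = labels)
}

# Core OPLS extraction on a centered X and centered univariate y.
# Returns weights/scores/loadings for n_ortho orthogonal components and
# one predictive component.
.opls_core <- function(x, y, n_ortho) {
  p <- ncol(x)
  w_ortho <- p_ortho <- matrix(0, p, 0)
  t_ortho <- matrix(0, nrow(x), 0)
  xd <- x
  for (j in seq_len(n_ortho)) {
    w <- crossprod(xd, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    tt <- xd %*% w
    pp <- crossprod(xd, tt) / sum(tt^2)
    wo <- pp - c(crossprod(w, pp)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break    # no orthogonal variation left
    wo <- wo / nwo
    to <- xd %*% wo
    po <- crossprod(xd, to) / sum(to^2)
    xd <- xd - to %*% t(po)
    w_ortho <- cbind(w_ortho, wo)
    p_ortho <- cbind(p_ortho, po)
    t_ortho <- cbind(t_ortho, to)
  }
  w <- crossprod(xd, y)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-14) stop("degenerate fit: X carries no covariance with y")
  w <- w / nw
  tt <- xd %*% w
  pp <- crossprod(xd, tt) / sum(tt^2)
  cc <- sum(y * tt) / sum(tt^2)
  list(w = drop(w), t = drop(tt), p = drop(pp), c = cc,
       w_ortho = w_ortho, p_ortho = p_ortho, t_ortho = t_ortho,
       x_filtered = xd)
}

# Apply a fitted orthogonal filter to new (train-centered) data and
# return the predictive score.
.opls_predict_t <- function(fit, xnew) {
  for (j in seq_len(ncol(fit$w_ortho))) {
    to <- xnew %*% fit$w_ortho[, j]
    xnew <- xnew - to %*% t(fit$p_ortho[, j])
  }
  drop(xnew %*% fit$w)
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.opls_q2 <- function(x, labels, y, n_ortho, cv_folds, seed) {
  .with_seed(seed, {
    fold <- .stratified_folds(labels, cv_folds)
    press <- 0
    tss <- 0
    for (f in seq_len(cv_folds)) {
      te <- fold == f
      if (!any(te)) next
      xtr <- x[!te, , drop = FALSE]
      ytr <- y[!te]
      ctr <- colMeans(xtr)
      mtr <- mean(ytr)
      fit <- .opls_core(sweep(xtr, 2, ctr, "-"), ytr - mtr, n_ortho)
      tte <- .opls_predict_t(fit, sweep(x[te, , drop = FALSE], 2, ctr, "-"))
      yhat <- tte * fit$c
      press <- press + sum((y[te] - mtr - yhat)^2)
      tss <- tss + sum((y[te] - mtr)^2)
    }
    1 - press / tss
  })
}

#' Two-class OPLS-DA with VIP scores and S-plot coordinates
#'
#' Fits orthogonal projections to latent structures discriminant
#' analysis with `n_ortho` orthogonal components and one predictive
#' component against a two-class label vector.  Expects log2-centered
#' intensities (see [log2_center()]).  The predictive score is oriented
#' so that the alphabetically later class has positive mean score.
#'
#' VIP is computed over the predictive component only, normalized so
#' that `mean(vip^2) == 1`; the S-plot reports, per metabolite, the
#' covariance (`p1`) and Pearson correlation (`pcorr`) of the
#' metabolite with the predictive score.
#'
#' @param mat Complete numeric matrix (samples x metabolites),
#'   log2-centered.
#' @param labels Two-class label vector, each class with >= 3 samples.
#' @param n_ortho Number of orthogonal components (>= 0, default 1).
#' @param cv_folds Folds for the Q2 cross-validation (default 7),
#'   stratified by class.
#' @param seed Seed controlling the fold assignment.
#' @return An object of class `oplsda_result` with elements
#'   `predictive_scores`, `orthogonal_scores`, `weights`, `loadings`,
#'   `vip`, `splot` (data.frame `p1`, `pcorr`), `r2y`, `q2`, `groups`.
#' @export
oplsda <- function(mat, labels, n_ortho = 1, cv_folds = 7, seed = 1L) {
  stopifnot(is.matrix(mat), is.numeric(mat), n_ortho >= 0)
  .stop_if_missing(mat, "fit OPLS-DA on")
  if (length(labels) != nrow(mat)) {
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(mat), ")")
  }
  enc <- .binary_y(labels)
  fit <- .opls_core(mat, enc$y, n_ortho)
  # orientation: later group positive
  if (mean(fit$t[enc$labels == enc$groups[2]]) < 0) {
    fit$t <- -fit$t
    fit$w <- -fit$w
    fit$p <- -fit$p
    fit$c <- -fit$c
  }
  p_m <- ncol(mat)
  vip <- sqrt(p_m) * abs(fit$w)   # single predictive component
  p1 <- drop(stats::cov(mat, fit$t))
  tsd <- stats::sd(fit$t)
  xsd <- apply(mat, 2, stats::sd)
  pcorr <- ifelse(xsd > 0, p1 / (xsd * tsd), 0)
  pcorr <- pmin(1, pmax(-1, pcorr))
  yhat <- fit$t * fit$c
  r2y <- 1 - sum((enc$y - yhat)^2) / sum(enc$y^2)
  q2 <- .opls_q2(mat, enc$labels, enc$y, n_ortho, cv_folds, seed)
  ids <- colnames(mat)
  structure(list(
    predictive_scores = stats::setNames(fit$t, rownames(mat)),
    orthogonal_scores = fit$t_ortho,
    weights = stats::setNames(fit$w, ids),
    loadings = stats::setNames(fit$p, ids),
    vip = stats::setNames(vip, ids),
    splot = data.frame(metabolite_id = ids, p1 = p1, pcorr = pcorr,
                       row.names = NULL, stringsAsFactors = FALSE),
    r2y = r2y, q2 = q2, groups = enc$groups, n_ortho = ncol(fit$t_ortho),
    y_coef = fit$c),
    class = "oplsda_result")
}

#' @export
print.oplsda_result <- function(x, ...) {
  cat("OPLS-DA:", x$groups[1], "vs", x$groups[2], "\n")
  cat(sprintf("  %d metabolites, %d orthogonal component(s)\n",
              length(x$vip), x$n_ortho))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f\n", x$r2y, x$q2))
  cat("  metabolites with VIP > 1:", sum(x$vip > 1), "\n")
  invisible(x)
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Recomputes Q2 under `n_perm` uniformly random permutations of the
#' class labels and reports the empirical upper-tail P-value
#' `(1 + #\{Q2_perm >= Q2_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams oplsda
#' @param n_perm Number of permutations (>= 19).
#' @return An object of class `permutation_result`: `observed_q2`,
#'   `permuted_q2` (length `n_perm`), `p_value`.
#' @export
permutation_test <- function(mat, labels, n_ortho = 1, n_perm = 99,
                             cv_folds = 7, seed = 1L) {
  if (n_perm < 19) stop("n_perm must be >= 19")
  obs <- oplsda(mat, labels, n_ortho = n_ortho, cv_folds = cv_folds,
                seed = seed)$q2
  perms <- .with_seed(seed, {
    replicate(n_perm, sample(as.character(labels)))
  })
  permuted <- vapply(seq_len(n_perm), function(i) {
    oplsda(mat, perms[, i], n_ortho = n_ortho, cv_folds = cv_folds,
           seed = seed)$q2
  }, 0)
  p <- (1 + sum(permuted >= obs)) / (n_perm + 1)
  structure(list(observed_q2 = obs, permuted_q2 = permuted, p_value = p),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed Q2 = %.3f, P = %.4g (%d perms)\n",
              x$observed_q2, x$p_value, length(x$permuted_q2)))
  invisible(x)
}
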