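# Matrix transforms applied ahead of modeling.  Two fixed branches:
# raw intensities are unit-variance scaled before PCA, and
# log2-transformed + mean-centered before OPLS-DA.  Imputation always
# comes first; the downstream transforms refuse matrices that still
# contain missing values, which enforces the impute -> transform order.

#' Half-minimum imputation of missing intensities
#'
#' Each missing cell is replaced by half the minimum positive
#' non-missing value of its metabolite column — the conventional
#' left-censoring assumption for peak areas below the detection limit.
#'
#' @param mat Abundance matrix (samples x metabolites, `NA` = missing).
#' @return The matrix with no missing values.
#' @export
impute_half_min <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (!anyNA(mat)) return(mat)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    nas <- is.na(col)
    if (!any(nas)) next
    pos <- col[!nas & col > 0]
    if (!length(pos)) {
      stop("cannot impute metabolite ", colnames(mat)[j],
           ": no positive non-missing value in its column")
    }
    mat[nas, j] <- min(pos) / 2
  }
  mat
}

.stop_if_missing <- function(mat, verb) {
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("cannot ", verb, " a matrix with missing values (first at sample ",
         rownames(mat)[idx[1]], ", metabolite ", colnames(mat)[idx[2]],
         "); run impute_half_min() first")
  }
  invisible(TRUE)
}

#' Unit-variance (auto) scaling
#'
#' Centers every metabolite column and divides by its sample standard
#' deviation (n-1 denominator).  Zero-variance columns are set to zero
#' and flagged in the `"zero_variance"` attribute rather than producing
#' NaNs.
#'
#' @param mat Complete (imputed) abundance matrix.
#' @return Scaled matrix; `attr(, "zero_variance")` is a named logical
#'   vector marking degenerate columns.
#' @export
uv_scale <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "unit-variance scale")
  mu <- colMeans(mat)
  sd_ <- apply(mat, 2, stats::sd)
  zero <- sd_ <= .Machine$double.eps * pmax(1, abs(mu))
  sd_[zero] <- 1
  out <- sweep(sweep(mat, 2, mu, "-"), 2, sd_, "/")
  out[, zero] <- 0
  names(zero) <- colnames(mat)
  attr(out, "zero_variance") <- zero
  out
}

#' log2 transform followed by mean centering
#'
#' Elementwise log2 then per-metabolite mean subtraction, the
#' preparation used ahead of OPLS-DA.  All values must be strictly
#' positive; a non-positive value signals that imputation was skipped
#' or the input is not a raw intensity matrix.
#'
#' @param mat Complete abundance matrix of positive intensities.
#' @return Transformed matrix with column means 0.
#' @export
log2_center <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "log2-transform")
  nonpos <- mat <= 0
  if (any(nonpos)) {
    idx <- which(nonpos, arr.ind = TRUE)[1, ]
    stop("non-positive intensity at sample ", rownames(mat)[idx[1]],
         ", metabolite ", colnames(mat)[idx[2]],
         "; log2 requires strictly positive values")
  }
  lg <- log2(mat)
  sweep(lg, 2, colMeans(lg), "-")
}
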