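# Metabolite selection logic: group-mean fold changes on the raw
# (imputed) intensity scale, differential / non-differential calls at
# the VIP and log2 fold-change thresholds, per-group top-k abundance
# cores, and the "essence" intersection — the metabolites that are both
# highly abundant in every group and non-differential in every
# reference-vs-concurrent comparison.

#' Per-metabolite fold change between two groups
#'
#' Ratio of the arithmetic mean intensity in `group_b` to the mean in
#' `group_a`, computed on the raw (imputed, untransformed) scale.
#'
#' @param mat Complete abundance matrix of positive intensities.
#' @param labels Group label per sample.
#' @param group_a Reference group (denominator).
#' @param group_b Contrast group (numerator).
#' @return Named numeric vector of fold changes, one per metabolite.
#' @export
fold_change <- function(mat, labels, group_a, group_b) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "compute fold changes on")
  labels <- as.character(labels)
  ia <- labels == group_a
  ib <- labels == group_b
  if (!any(ia)) stop("empty group: ", group_a)
  if (!any(ib)) stop("empty group: ", group_b)
  ma <- colMeans(mat[ia, , drop = FALSE])
  mb <- colMeans(mat[ib, , drop = FALSE])
  if (any(ma <= 0) || any(mb <= 0)) {
    bad <- colnames(mat)[which(ma <= 0 | mb <= 0)[1]]
    stop("non-positive group mean for metabolite ", bad,
         "; fold changes need imputed positive intensities")
  }
  mb / ma
}

#' Call differential and non-differential metabolites
#'
#' Assigns each metabolite one of three statuses from its VIP score and
#' fold change, using strict inequalities:
#' `differential` when `vip > vip_threshold` and
#' `|log2(fc)| > log2fc_threshold`; `nondifferential` when
#' `vip < vip_threshold` and the fold change is inside the band;
#' otherwise `indeterminate`.  The two definitions deliberately do not
#' partition the plane — boundary metabolites belong to neither set.
#'
#' With `symmetric = TRUE` (default) the non-differential band is
#' two-sided, `|log2(fc)| < log2fc_threshold`; with `symmetric = FALSE`
#' only the upper bound is applied (`log2(fc) < log2fc_threshold`), so
#' strong down-regulation still counts as non-differential.
#'
#' @param vip Named VIP vector (from [oplsda()]).
#' @param fc Named fold-change vector (from [fold_change()]), aligned
#'   with `vip`.
#' @param vip_threshold VIP cutoff (default 1).
#' @param log2fc_threshold |log2 fold change| cutoff (default 1, i.e.
#'   fold change 2).
#' @param symmetric Whether the non-differential band is two-sided.
#' @return A data.frame with columns `metabolite_id`, `vip`,
#'   `fold_change`, `log2_fc`, `status`.
#' @export
call_differential <- function(vip, fc, vip_threshold = 1,
                              log2fc_threshold = 1, symmetric = TRUE) {
  if (length(vip) != length(fc)) {
    stop("vip and fc lengths differ (", length(vip), " vs ", length(fc), ")")
  }
  if (!is.null(names(vip)) && !is.null(names(fc)) &&
      !identical(names(vip), names(fc))) {
    stop("vip and fc are not aligned on the same metabolite order")
  }
  stopifnot(vip_threshold > 0, log2fc_threshold > 0)
  l2 <- log2(fc)
  inside <- if (symmetric) abs(l2) < log2fc_threshold else l2 < log2fc_threshold
  status <- rep("indeterminate", length(vip))
  status[vip > vip_threshold & abs(l2) > log2fc_threshold] <- "differential"
  status[vip < vip_threshold & inside] <- "nondifferential"
  ids <- names(vip)
  if (is.null(ids)) ids <- names(fc)
  if (is.null(ids)) ids <- as.character(seq_along(vip))
  data.frame(metabolite_id = ids,
             vip = unname(vip), fold_change = unname(fc),
             log2_fc = unname(l2), status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group top-k abundance sets and their intersection
#'
#' Ranks metabolites within each group by mean raw intensity
#' (descending, ties broken by metabolite id), takes the top `k` per
#' group, and intersects across all groups.
#'
#' @param mat Complete abundance matrix.
#' @param labels Group label per sample.
#' @param k Number of metabolites per group (default 100).
#' @return List with `per_group` (named list of character vectors, in
#'   rank order) and `core` (the intersection, sorted).
#' @export
top_k_abundant_core <- function(mat, labels, k = 100) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  .stop_if_missing(mat, "rank abundances on")
  if (k < 1 || k > ncol(mat)) {
    stop("k must be in 1..", ncol(mat))
  }
  labels <- as.character(labels)
  groups <- sort(unique(labels), method = "radix")
  ids <- colnames(mat)
  per_group <- lapply(groups, function(g) {
    m <- colMeans(mat[labels == g, , drop = FALSE])
    ids[order(-m, ids, method = "radix")][seq_len(k)]
  })
  names(per_group) <- groups
  core <- sort(Reduce(intersect, per_group), method = "radix")
  list(per_group = per_group, core = core)
}

#' The essence set: abundant everywhere, differential nowhere
#'
#' Intersects the per-comparison non-differential sets into
#' `nondiff_core` and then intersects with the top-k abundance core.
#'
#' @param nondiff_sets Named list of character vectors, one per
#'   comparison (e.g. `IPBS_vs_PST`), each the non-differential
#'   metabolites of that comparison.
#' @param topk_core Character vector, the cross-group top-k
#'   intersection (see [top_k_abundant_core()]).
#' @param required Optional character vector of comparison names that
#'   must be present in `nondiff_sets`; missing ones raise an error.
#' @return List with `nondiff_core`, `topk_core`, `essence` (all sorted
#'   character vectors).
#' @export
essence_set <- function(nondiff_sets, topk_core, required = NULL) {
  if (!length(nondiff_sets)) stop("no non-differential sets supplied")
  if (!is.null(required)) {
    miss <- setdiff(required, names(nondiff_sets))
    if (length(miss)) {
      stop("missing non-differential set(s) for comparison(s): ",
           paste(miss, collapse = ", "))
    }
  }
  nondiff_core <- sort(Reduce(intersect, nondiff_sets), method = "radix")
  list(nondiff_core = nondiff_core,
       topk_core = sort(topk_core, method = "radix"),
       essence = sort(intersect(nondiff_core, topk_core), method = "radix"))
}
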