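# Over-representation analysis of a metabolite set against pathway
# compound sets.  The P-value is the exact hypergeometric upper tail,
# accumulated on the log scale for numerical stability; the background
# is the set of detected metabolites that carry a compound-key
# annotation.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items
#' from a population of `N` of which `K` are marked.  Terms are
#' accumulated from log binomial coefficients (log-sum-exp), so large
#' populations do not underflow.  Vectorized over `k`.
#'
#' @param N Population (background) size.
#' @param K Marked (pathway) members in the population.
#' @param n Draw (query) size.
#' @param k Observed overlap(s); each must lie in `0..min(K, n)`.
#' @return Probability vector, one element per `k`, each in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (length(N) != 1 || length(K) != 1 || length(n) != 1) {
    stop("N, K and n must be scalars")
  }
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    stop("require 0 <= K <= N and 0 <= n <= N (got N=", N,
         ", K=", K, ", n=", n, ")")
  }
  kmax <- min(K, n)
  if (any(k < 0 | k > kmax)) {
    stop("k must lie in 0..min(K, n) = 0..", kmax)
  }
  i <- 0:kmax
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  # upper tails from the top, on the log scale
  tail_from <- rev(cumsum(rev(exp(logp - m))))
  pmin(1, exp(m) * tail_from[k + 1])
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the query metabolite
#' set against the background, via the hypergeometric upper tail.
#' Metabolites without a compound-key annotation are dropped from both
#' query and background before counting; pathways with no annotated
#' background member are not tested.  P-values are Benjamini-Hochberg
#' adjusted across the tested pathways.
#'
#' @param query Character vector of metabolite ids; must be a subset of
#'   `background`.
#' @param background Character vector of metabolite ids (typically all
#'   detected metabolites).
#' @param annotation Annotation data.frame with `metabolite_id` and
#'   `compound_key` columns (see [read_annotation()]).
#' @param pathways Pathway data.frame (see [read_pathway_gmt()]); the
#'   `members` sets are compound keys.
#' @param factor Enrichment factor definition: `"query"` reports
#'   `k / n` (the gene-ratio convention), `"pathway"` reports `k / K`.
#' @return A data.frame sorted by `p_value` with columns `pathway_id`,
#'   `pathway_name`, `N`, `K`, `n`, `k`, `enrichment_factor`,
#'   `p_value`, `adjusted_p`.
#' @export
enrich <- function(query, background, annotation, pathways,
                   factor = c("query", "pathway")) {
  factor <- match.arg(factor)
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop("query metabolites missing from background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  if (!all(c("metabolite_id", "compound_key") %in% colnames(annotation))) {
    stop("annotation needs metabolite_id and compound_key columns")
  }
  keys <- stats::setNames(annotation$compound_key, annotation$metabolite_id)
  keys <- keys[!is.na(keys) & nzchar(keys)]
  bg <- background[background %in% names(keys)]
  q <- query[query %in% names(keys)]
  n_dropped <- (length(background) - length(bg)) + (length(query) - length(q))
  N <- length(bg)
  n <- length(q)
  bg_keys <- keys[bg]
  q_keys <- keys[q]
  rows <- lapply(seq_len(nrow(pathways)), function(i) {
    members <- pathways$members[[i]]
    K <- sum(bg_keys %in% members)
    if (K == 0) return(NULL)
    k <- sum(q_keys %in% members)
    p <- if (n == 0) 1 else hypergeom_upper_tail(N, K, n, k)
    ef <- if (factor == "query") {
      if (n == 0) 0 else k / n
    } else {
      k / K
    }
    data.frame(pathway_id = pathways$pathway_id[i],
               pathway_name = pathways$pathway_name[i],
               N = N, K = K, n = n, k = k,
               enrichment_factor = ef, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(pathway_id = character(), pathway_name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), enrichment_factor = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_unannotated_dropped") <- n_dropped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated_dropped") <- n_dropped
  out
}
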