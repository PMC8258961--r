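#' Annotation over-representation test
#'
#' One-sided exact test of whether each annotation term is
#' over-represented in a query set relative to a background: the p-value
#' is the upper hypergeometric tail P(X >= k) with k query hits in a term
#' of size K, a query of size n, and a background of size N. P-values are
#' corrected across tested terms with Benjamini-Hochberg, and rows with
#' FDR below the cutoff are flagged. Terms intersecting the background in
#' fewer than `min_term_size` members are untestable and skipped.
#'
#' @param query Character vector of query accessions (must be contained
#'   in the background).
#' @param annotations List of annotation sets as produced by
#'   [read_gmt()].
#' @param background Character vector of background accessions; defaults
#'   to the union of all annotation members.
#' @param fdr_cutoff Significance cutoff on the FDR (default 0.01).
#' @param min_term_size Minimum in-background term size (default 2).
#' @return Data frame with one row per tested term: `term_id`,
#'   `term_name`, `k_query`, `n_query`, `K_background`, `N_background`,
#'   `fold_enrichment`, `p_value`, `fdr`, `significant`; sorted by
#'   p-value (ties by term id). Attribute `n_skipped` counts skipped
#'   terms.
#' @export
overrepresentation <- function(query, annotations, background = NULL,
                               fdr_cutoff = 0.01, min_term_size = 2) {
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query set", call. = FALSE)
  if (is.null(background)) {
    background <- unique(unlist(lapply(annotations, `[[`, "members"),
                                use.names = FALSE))
  }
  background <- unique(as.character(background))
  offenders <- setdiff(query, background)
  if (length(offenders) > 0) {
    stop("query accession(s) not in background: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) ", ...", call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  rows <- list()
  n_skipped <- 0L
  for (set in annotations) {
    members <- intersect(set$members, background)
    K <- length(members)
    if (K < min_term_size) {
      n_skipped <- n_skipped + 1L
      next
    }
    k <- length(intersect(query, members))
    # upper tail P(X >= k) of the hypergeometric law
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = set$term_id, term_name = set$term_name,
      k_query = k, n_query = n, K_background = K, N_background = N,
      fold_enrichment = (k / n) / (K / N),
      p_value = p,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    stop("no testable annotation terms (all below min_term_size)",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_cutoff
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
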