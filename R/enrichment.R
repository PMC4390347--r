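#' Pool per-dose hit partitions into a phenotype category
#'
#' Enrichment is evaluated on four phenotype categories — increased/decreased
#' viability and increased/decreased expression — with the hits of all doses
#' pooled (union) within each category.
#'
#' @param hit_calls A `hit_calls` object (from [call_viability_hits()] or
#'   [call_expression_hits()]).
#' @param category One of `"increased"`, `"decreased"`: the direction whose
#'   per-dose partitions are pooled.
#' @return Sorted character vector of gene symbols.
#' @export
pool_hits <- function(hit_calls, category = c("increased", "decreased")) {
  stopifnot(inherits(hit_calls, "hit_calls"))
  category <- match.arg(category)
  sel <- grepl(paste0(":", category, "$"), names(hit_calls$partitions))
  sort(unique(unlist(hit_calls$partitions[sel], use.names = FALSE)))
}

#' Filtered hypergeometric over-representation of a hit list
#'
#' For each gene set, counts the overlap `k` between the hits and the set's
#' members within the screened background of `N` genes (annotations are
#' intersected with the background before counting, so the population size
#' `K` has "genes of this term that were actually screened" semantics). Terms
#' are kept only if `K >= min_population` and `k >= min_hit_genes`; the
#' one-sided hypergeometric tail `P(X >= k)` is computed for the survivors and
#' adjusted across them (the family size equals the number of surviving
#' terms).
#'
#' Gene symbols are matched case-insensitively (symbol capitalization varies
#' across annotation sources) but reported with the case of the hit list.
#'
#' @param hits Character vector of hit gene symbols; must be a subset of
#'   `background`.
#' @param background Character vector of all screened genes (the analysis
#'   set, not the genome).
#' @param sets A `gene_set_collection` from [read_gmt()] (or any named list of
#'   gene vectors).
#' @param min_population Minimum screened genes per term (default 3).
#' @param min_hit_genes Minimum hit genes per term (default 2).
#' @param adjust Multiplicity adjustment: `"BH"` (default) or `"bonferroni"`.
#' @return Data frame sorted by `q` then `p`, one row per surviving term:
#'   `term_id`, `term_name`, `hit_genes` (comma-separated), `k`, `K`, `n`,
#'   `N`, `p`, `q`.
#' @examples
#' sets <- list(termA = c("g1", "g2", "g3"))
#' enrich(c("g1", "g2", "g5", "g6"), paste0("g", 1:10), sets)
#' @export
enrich <- function(hits, background, sets, min_population = 3,
                   min_hit_genes = 2, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  hits <- unique(hits)
  background <- unique(background)
  bad <- setdiff(toupper(hits), toupper(background))
  if (length(bad) > 0) {
    ts_error("validation_error",
             paste("hit gene(s) not in background:",
                   paste(head(bad, 5), collapse = ", ")))
  }
  descs <- attr(sets, "descriptions")
  bg_upper <- toupper(background)
  hit_upper <- toupper(hits)
  n <- length(hits)
  N <- length(background)

  rows <- lapply(names(sets), function(term) {
    members <- unique(toupper(sets[[term]]))
    in_bg <- intersect(members, bg_upper)
    K <- length(in_bg)
    overlap <- intersect(hit_upper, in_bg)
    k <- length(overlap)
    if (K < min_population || k < min_hit_genes) return(NULL)
    data.frame(
      term_id = term,
      term_name = if (!is.null(descs)) descs[[term]] %||% NA_character_ else NA_character_,
      hit_genes = paste(sort(hits[hit_upper %in% overlap]), collapse = ","),
      k = k, K = K, n = n, N = N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      hit_genes = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = if (adjust == "BH") "BH" else "bonferroni")
  out <- out[order(out$q, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique-gene summary over labelled hit partitions
#'
#' Reports per-partition gene counts, the size of the deduplicated union, and
#' the genes shared by every partition.
#'
#' @param partitions Named list of character vectors of gene symbols.
#' @return A list with `counts` (named integer vector), `union` (sorted gene
#'   vector), `n_union`, and `intersection` (genes present in all
#'   partitions).
#' @export
unique_gene_summary <- function(partitions) {
  stopifnot(is.list(partitions))
  partitions <- lapply(partitions, function(g) sort(unique(g)))
  uni <- sort(unique(unlist(partitions, use.names = FALSE)))
  inter <- if (length(partitions) == 0) character(0) else {
    Reduce(intersect, partitions)
  }
  list(counts = vapply(partitions, length, integer(1)),
       union = uni, n_union = length(uni),
       intersection = sort(inter))
}
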