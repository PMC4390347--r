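#' Duplicate concordance of a screen assay
#'
#' Pearson (or Spearman) correlation between duplicate 1 and duplicate 2 of a
#' per-clone metric, per dose contrast. For `assay = "viability"` the metric
#' is the per-duplicate change in percent viability (dose well minus the
#' clone's duplicate-averaged 0-Gy reference); for `assay = "betagal"` it is
#' the per-duplicate log10 ratio of normalized beta-gal expression to the
#' averaged reference.
#'
#' @param dataset A [screen_dataset()] with (at least) duplicates 1 and 2.
#' @param assay `"viability"` or `"betagal"`.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return Data frame with one row per positive dose: `assay`, `dose_gy`,
#'   `r`, `n_pairs`, `excluded` (count of clones without both duplicates or
#'   with unusable values).
#' @export
duplicate_correlation <- function(dataset, assay = c("viability", "betagal"),
                                  method = c("pearson", "spearman")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  assay <- match.arg(assay)
  method <- match.arg(method)
  rec <- dataset$records
  if (assay == "betagal") rec <- rec[!rec$is_wildtype, , drop = FALSE]
  doses <- setdiff(dataset$dose_set, 0)

  metric <- if (assay == "viability") {
    percent_viability(rec$dead_rlu, rec$total_rlu)
  } else {
    live <- rec$total_rlu - rec$dead_rlu
    ifelse(live > 0 & is.finite(rec$betagal_rlu),
           rec$betagal_rlu / live, NA_real_)
  }

  # duplicate-averaged 0-Gy reference per clone
  ref_rows <- rec$dose_gy == 0
  ref <- tapply(metric[ref_rows], rec$clone_id[ref_rows], mean)

  out <- lapply(doses, function(d) {
    sel <- rec$dose_gy == d & rec$replicate %in% c(1L, 2L)
    sub <- rec[sel, , drop = FALSE]
    m <- metric[sel]
    r0 <- as.numeric(ref[sub$clone_id])
    val <- if (assay == "viability") m - r0 else {
      ifelse(m > 0 & r0 > 0, log10(m / r0), NA_real_)
    }
    d1 <- val[sub$replicate == 1L][match(unique(sub$clone_id),
                                         sub$clone_id[sub$replicate == 1L])]
    d2 <- val[sub$replicate == 2L][match(unique(sub$clone_id),
                                         sub$clone_id[sub$replicate == 2L])]
    ok <- is.finite(d1) & is.finite(d2)
    n_pairs <- sum(ok)
    r <- if (n_pairs >= 2) stats::cor(d1[ok], d2[ok], method = method) else NA_real_
    data.frame(assay = assay, dose_gy = d, r = r, n_pairs = n_pairs,
               excluded = length(unique(sub$clone_id)) - n_pairs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold change from delta-delta-Ct qPCR records
#'
#' Delta Ct per condition is computed by subtracting the gene-of-interest Ct
#' from the reference-gene (e.g. Gapdh) Ct — note this is the reverse of the
#' more common gene-minus-reference orientation, so a *positive* ddCt means
#' *up*-regulation. ddCt is the irradiated minus unirradiated delta Ct, and
#' the fold change is `2^ddCt`.
#'
#' @param unirradiated,irradiated Lists or one-row data frames with fields
#'   `gene`, `ct_gene`, `ct_reference` (cycle thresholds, positive).
#' @return A list with `dct_unirradiated`, `dct_irradiated`, `ddct`, and
#'   `fold_change`.
#' @examples
#' ddct_fold_change(list(gene = "Vcan", ct_gene = 25, ct_reference = 20),
#'                  list(gene = "Vcan", ct_gene = 23, ct_reference = 20))$fold_change  # 4
#' @export
ddct_fold_change <- function(unirradiated, irradiated) {
  for (rec in list(unirradiated, irradiated)) {
    if (!all(c("gene", "ct_gene", "ct_reference") %in% names(rec))) {
      ts_error("validation_error",
               "records need fields gene, ct_gene, ct_reference")
    }
    if (any(unlist(rec[c("ct_gene", "ct_reference")]) <= 0)) {
      ts_error("validation_error", "Ct values must be positive")
    }
  }
  if (unirradiated$gene != irradiated$gene) {
    ts_error("validation_error",
             sprintf("gene mismatch: %s vs %s", unirradiated$gene,
                     irradiated$gene))
  }
  dct_u <- unirradiated$ct_reference - unirradiated$ct_gene
  dct_i <- irradiated$ct_reference - irradiated$ct_gene
  ddct <- dct_i - dct_u
  list(dct_unirradiated = dct_u, dct_irradiated = dct_i,
       ddct = ddct, fold_change = 2^ddct)
}

#' Assemble a structured run report
#'
#' Bundles the pipeline outputs with the run configuration and seeds into a
#' single document sufficient to re-run the analysis identically.
#'
#' @param viability [viability_results()] output (or `NULL`).
#' @param expression [expression_results()] output (or `NULL`).
#' @param enrichment A named list of [enrich()] tables (or `NULL`).
#' @param qc [duplicate_correlation()] output (or `NULL`).
#' @param config The generator or run configuration (list).
#' @return A list of class `screen_report` with sections `meta` (package
#'   version, date), `config`, `nulls`, `viability`, `expression`,
#'   `enrichment`, `qc`, and `summary` (hit counts).
#' @export
build_report <- function(viability = NULL, expression = NULL,
                         enrichment = NULL, qc = NULL, config = NULL) {
  null_summ <- function(res) {
    nl <- attr(res, "nulls")
    if (is.null(nl)) return(NULL)
    lapply(nl, function(m) list(mu = m$mu, sigma = m$sigma, n_used = m$n_used,
                                source = m$source))
  }
  summary <- list()
  if (!is.null(viability)) {
    calls <- call_viability_hits(viability, attr(viability, "alpha") %||% 0.01)
    summary$viability_hits <- as.list(calls$counts)
    summary$viability_unique_genes <- calls$n_unique
  }
  if (!is.null(expression)) {
    calls <- call_expression_hits(expression, attr(expression, "alpha") %||% 0.01)
    summary$expression_hits <- as.list(calls$counts)
    summary$expression_unique_genes <- calls$n_unique
  }
  structure(list(
    meta = list(package = "trapscreen",
                version = as.character(utils::packageVersion("trapscreen")),
                generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    config = if (!is.null(config)) unclass(config) else NULL,
    nulls = list(viability = null_summ(viability),
                 expression = null_summ(expression)),
    viability = if (!is.null(viability)) as.data.frame(viability) else NULL,
    expression = if (!is.null(expression)) as.data.frame(expression) else NULL,
    enrichment = enrichment,
    qc = qc,
    summary = summary
  ), class = "screen_report")
}

#' Write a run report as JSON
#'
#' @param report A [build_report()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen analysis report —", x$meta$package, x$meta$version, "\n")
  if (length(x$summary) > 0) {
    cat(sprintf("  viability hits: %s unique genes\n",
                x$summary$viability_unique_genes %||% "NA"))
    cat(sprintf("  expression hits: %s unique genes\n",
                x$summary$expression_unique_genes %||% "NA"))
  }
  invisible(x)
}
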