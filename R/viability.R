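#' Percent viability from dead-cell and total-cell luminescence
#'
#' The cytotoxicity assay reads the dead-cell protease signal first and the
#' total signal after lysis, so percent viability is
#' `(total - dead) / total`, the fraction of cells that are alive.
#'
#' @param dead_rlu Dead-cell relative light units (>= 0).
#' @param total_rlu Total-cell relative light units (> 0). Vectors recycle as
#'   usual.
#' @return Viability as a fraction in `[0, 1]`.
#' @examples
#' percent_viability(400, 1000)  # 0.6
#' @export
percent_viability <- function(dead_rlu, total_rlu) {
  if (any(!is.finite(total_rlu) | total_rlu <= 0)) {
    ts_error("undefined_well_error", "total_rlu must be positive")
  }
  if (any(!is.finite(dead_rlu) | dead_rlu < 0)) {
    ts_error("qc_error", "dead_rlu must be non-negative")
  }
  if (any(dead_rlu > total_rlu)) {
    ts_error("qc_error", "dead_rlu exceeds total_rlu (failed QC well)")
  }
  (total_rlu - dead_rlu) / total_rlu
}

#' Change in percent viability between a dose and the 0-Gy reference
#'
#' @param v_dose Viability fraction at the irradiated dose.
#' @param v_ref Viability fraction at 0 Gy.
#' @return Signed difference `v_dose - v_ref` in `[-1, 1]`.
#' @export
delta_viability <- function(v_dose, v_ref) {
  stopifnot(all(v_dose >= 0 & v_dose <= 1, na.rm = TRUE),
            all(v_ref >= 0 & v_ref <= 1, na.rm = TRUE))
  v_dose - v_ref
}

#' Fit the wild-type replicate null for delta viability
#'
#' Wild-type wells carry no trapped gene, so their dose-contrast changes in
#' viability represent the variability expected by chance alone. The null is
#' their sample mean and standard deviation (n-1 denominator; the replicate
#' set is small, typically ~22 wells).
#'
#' @param wt_deltas Numeric vector of wild-type delta-viability values for one
#'   dose contrast.
#' @param ids Optional identifiers recorded in the model.
#' @return A [new_null_model()] with `source = "wt_replicates"`.
#' @export
fit_wt_null <- function(wt_deltas, ids = NULL) {
  wt_deltas <- wt_deltas[is.finite(wt_deltas)]
  if (length(wt_deltas) < 2) {
    ts_error("insufficient_null_error",
             "need >= 2 finite wild-type delta-viability values")
  }
  sigma <- stats::sd(wt_deltas)
  if (sigma == 0) {
    ts_error("degenerate_null_error",
             "wild-type deltas are constant (zero null scale)")
  }
  new_null_model(mean(wt_deltas), sigma, length(wt_deltas),
                 "wt_replicates", inlier_ids = ids)
}

#' Z-score of a statistic against a null model
#'
#' `z = (x - mu) / sigma` with the null location and scale; the sign of the
#' deviation is preserved.
#'
#' @param x Statistic value(s) (delta viability or log10 expression ratio).
#' @param null A [new_null_model()].
#' @return Standard-normal-unit score(s).
#' @export
z_score <- function(x, null) {
  stopifnot(inherits(null, "null_model"))
  (x - null$mu) / null$sigma
}

#' Two-tailed normal p-value of a Z-score
#'
#' `p = 2 * Phi(-|z|)` using the full-precision normal tail (no series
#' truncation at large `|z|`). For finite `z` the result is never exactly 0:
#' below the double floor the smallest positive double is returned, and the
#' exact magnitude is available via [log10_two_tailed_p()].
#'
#' @param z Z-score(s).
#' @return Two-tailed probability in `(0, 1]`.
#' @examples
#' two_tailed_p(0)         # 1
#' two_tailed_p(-4.41953)  # 9.89e-06
#' @export
two_tailed_p <- function(z) {
  stopifnot(all(is.finite(z)))
  p <- 2 * stats::pnorm(-abs(z))
  p[p > 1] <- 1
  p[p == 0] <- .Machine$double.xmin
  p
}

#' Log10 of the two-tailed normal p-value
#'
#' Computed on the log scale, so it stays exact far beyond the underflow
#' point of [two_tailed_p()].
#'
#' @param z Z-score(s).
#' @return `log10(2 * Phi(-|z|))`.
#' @export
log10_two_tailed_p <- function(z) {
  stopifnot(all(is.finite(z)))
  lp <- (log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  pmin(lp, 0)
}

# Average duplicate wells to one metric value per clone x dose.
# f maps the well rows to a numeric metric; returns data frame
# clone_id, gene_symbol, is_wildtype, dose_gy, value, n_wells.
aggregate_duplicates <- function(records, values) {
  key <- interaction(records$clone_id, records$dose_gy, drop = TRUE)
  agg <- data.frame(
    clone_id = tapply(records$clone_id, key, `[`, 1L),
    gene_symbol = tapply(records$gene_symbol, key, `[`, 1L),
    is_wildtype = as.logical(tapply(records$is_wildtype, key, `[`, 1L)),
    dose_gy = as.numeric(tapply(records$dose_gy, key, `[`, 1L)),
    value = as.numeric(tapply(values, key, mean)),
    n_wells = as.integer(tapply(values, key, length)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  agg
}

# Wide per-clone table of a duplicate-averaged metric: one row per clone,
# columns v_ref (0 Gy) and one per positive dose.
contrast_table <- function(agg, doses) {
  ref <- agg[agg$dose_gy == 0, c("clone_id", "gene_symbol", "is_wildtype", "value")]
  names(ref)[names(ref) == "value"] <- "ref"
  out <- ref
  for (d in doses) {
    dd <- agg[agg$dose_gy == d, c("clone_id", "value")]
    names(dd)[2] <- paste0("dose_", d)
    out <- merge(out, dd, by = "clone_id", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Per-clone viability statistics with wild-type-null Z-scores
#'
#' For every clone and positive dose: percent viability per well, duplicates
#' averaged at the viability level, delta V = mean viability at dose minus
#' mean viability at 0 Gy, Z-score against the per-dose wild-type replicate
#' null, two-tailed p-value and direction. Direction is classified by the sign
#' of `delta_v - mu_wt` (deviation from the wild-type drift), so a clone
#' matching wild-type behaviour is not called directional.
#'
#' @param dataset A [screen_dataset()].
#' @param alpha Significance cut-off for `is_hit` (two-tailed p), default 0.01.
#' @param average Either `"viability"` (default; duplicates averaged at the
#'   percent-viability level) or `"rlu"` (average raw dead/total RLU first).
#' @return A data frame of class `viability_results` with one row per clone
#'   per dose contrast: `clone_id`, `gene_symbol`, `dose_gy`, `ref_dose`,
#'   `v_ref`, `v_dose`, `delta_v`, `z`, `p`, `log10_p`, `direction`,
#'   `is_hit`. Per-dose null models are attached as attribute `"nulls"`
#'   (a named list).
#' @export
viability_results <- function(dataset, alpha = 0.01,
                              average = c("viability", "rlu")) {
  stopifnot(inherits(dataset, "screen_dataset"))
  average <- match.arg(average)
  rec <- dataset$records
  doses <- setdiff(dataset$dose_set, 0)
  if (length(doses) == 0) {
    ts_error("validation_error", "dataset has no positive dose to contrast")
  }

  if (average == "viability") {
    v <- percent_viability(rec$dead_rlu, rec$total_rlu)
    agg <- aggregate_duplicates(rec, v)
  } else {
    dead <- aggregate_duplicates(rec, rec$dead_rlu)
    total <- aggregate_duplicates(rec, rec$total_rlu)
    agg <- dead
    agg$value <- percent_viability(dead$value, total$value)
  }
  wide <- contrast_table(agg, doses)

  nulls <- list()
  out <- list()
  for (d in doses) {
    col <- paste0("dose_", d)
    dv <- delta_viability(wide[[col]], wide$ref)
    wt <- wide$is_wildtype & is.finite(dv)
    nulls[[as.character(d)]] <- fit_wt_null(dv[wt], ids = wide$clone_id[wt])
    null <- nulls[[as.character(d)]]
    cl <- !wide$is_wildtype & is.finite(dv)
    z <- z_score(dv[cl], null)
    p <- two_tailed_p(z)
    out[[as.character(d)]] <- data.frame(
      clone_id = wide$clone_id[cl],
      gene_symbol = wide$gene_symbol[cl],
      dose_gy = d,
      ref_dose = 0,
      v_ref = wide$ref[cl],
      v_dose = wide[[col]][cl],
      delta_v = dv[cl],
      z = z,
      p = p,
      log10_p = log10_two_tailed_p(z),
      direction = ifelse(z > 0, "increased", "decreased"),
      is_hit = p < alpha,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, nulls = nulls, alpha = alpha,
            class = c("viability_results", "data.frame"))
}

#' Partition significant viability hits by dose contrast and direction
#'
#' Applies the two-tailed cut-off `p < alpha` and partitions the hits by
#' `(dose, direction)`, reporting per-partition gene lists and counts plus
#' the deduplicated union of gene symbols across partitions.
#'
#' @param results A data frame with columns `gene_symbol`, `dose_gy`, `z` (or
#'   `direction`) and `p` — typically [viability_results()] output, but any
#'   table of per-clone statistics works (e.g. a published hit table).
#' @param alpha Significance cut-off, default 0.01.
#' @return A list of class `hit_calls`: `partitions` (named list of gene
#'   vectors, names like `"0.5:increased"`), `counts` (named integer vector),
#'   `unique_genes` (deduplicated union), `n_unique`, and `alpha`.
#' @examples
#' calls <- call_viability_hits(viability_hit_table())
#' calls$counts     # 5 / 16 / 7
#' calls$n_unique   # 28
#' @export
call_viability_hits <- function(results, alpha = 0.01) {
  call_hits(results, alpha = alpha)
}

# Shared hit partitioning for both assays.
call_hits <- function(results, alpha = 0.01) {
  stopifnot(is.data.frame(results) || inherits(results, "data.frame"))
  results <- as.data.frame(results)
  if (nrow(results) > 0 && !"direction" %in% names(results)) {
    results$direction <- ifelse(results$z > 0, "increased", "decreased")
  }
  hits <- results[!is.na(results$p) & results$p < alpha, , drop = FALSE]
  partitions <- list()
  if (nrow(hits) > 0) {
    key <- paste(hits$dose_gy, hits$direction, sep = ":")
    for (k in unique(key)) {
      partitions[[k]] <- sort(unique(hits$gene_symbol[key == k]))
    }
  }
  uniq <- sort(unique(hits$gene_symbol))
  structure(list(partitions = partitions,
                 counts = vapply(partitions, length, integer(1)),
                 unique_genes = uniq,
                 n_unique = length(uniq),
                 alpha = alpha),
            class = "hit_calls")
}

#' @export
print.hit_calls <- function(x, ...) {
  cat(sprintf("Hit calls at alpha = %g: %d unique gene(s)\n", x$alpha, x$n_unique))
  for (k in names(x$partitions)) {
    cat(sprintf("  %-18s %3d  %s\n", k, length(x$partitions[[k]]),
                paste(head(x$partitions[[k]], 8), collapse = ", ")))
  }
  invisible(x)
}
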