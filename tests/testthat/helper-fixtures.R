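# Shared fixture builders: all data are generated in code.

# Minimal hand-built dataset: `n_clones` mutant clones plus `n_wt` wild-type
# units, two duplicates, doses 0 and 4 Gy, with exact viability fractions
# supplied per unit x dose (no noise). total RLU fixed at 1000.
make_dataset <- function(v_by_unit, expr_by_unit = NULL, doses = c(0, 4)) {
  rows <- list()
  for (u in names(v_by_unit)) {
    wt <- startsWith(u, "WT")
    for (d in doses) {
      v <- v_by_unit[[u]][[as.character(d)]]
      e <- if (!wt && !is.null(expr_by_unit)) {
        expr_by_unit[[u]][[as.character(d)]]
      } else NA_real_
      for (r in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          clone_id = u, gene_symbol = if (wt) "WT" else u,
          dose_gy = d, replicate = r,
          dead_rlu = (1 - v) * 1000, total_rlu = 1000,
          betagal_rlu = if (is.na(e)) NA_real_ else e * v * 1000,
          is_wildtype = wt, stringsAsFactors = FALSE)
      }
    }
  }
  screen_dataset(do.call(rbind, rows), require_betagal = FALSE)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability that a size-n draw from N items, K of them special, contains
# at least k specials. Counts every size-n subset explicitly.
hyper_tail_enum <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  special <- seq_len(K)
  hits <- colSums(matrix(subsets %in% special, nrow = n))
  mean(hits >= k)
}

# Reference implementation of the naive (non-robust) location estimate used
# as the comparison arm in robustness checks.
naive_location <- function(x) mean(x)
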