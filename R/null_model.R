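#' Null model for a screen statistic
#'
#' A location/scale summary of the null distribution of a per-clone statistic:
#' the change in percent viability (delta V, a fraction) or the log10 dose
#' ratio of normalized beta-gal expression. The null is either estimated from
#' wild-type replicate wells ([fit_wt_null()]), from the clone population by
#' robust consensus ([ransac_null()]), or back-derived from a published table
#' of paired statistic/Z values ([implied_null()]).
#'
#' @param mu Location of the null distribution.
#' @param sigma Scale (standard deviation) of the null; must be positive.
#' @param n_used Number of values the estimate is based on.
#' @param source One of `"wt_replicates"`, `"ransac_consensus"`,
#'   `"table_backfit"`.
#' @param inlier_ids Identifiers of the values used in the estimate (for
#'   consensus fits, the inlier set).
#'
#' @return An object of class `null_model`: a list with fields `mu`, `sigma`,
#'   `n_used`, `source`, `inlier_ids`.
#' @seealso [fit_wt_null()], [ransac_null()], [z_score()]
#' @export
new_null_model <- function(mu, sigma, n_used, source, inlier_ids = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0) {
    ts_error("degenerate_null_error",
             sprintf("null scale must be positive, got %g", sigma))
  }
  if (n_used < 2) {
    ts_error("insufficient_null_error",
             sprintf("null model needs >= 2 values, got %d", n_used))
  }
  source <- match.arg(source, c("wt_replicates", "ransac_consensus",
                                "table_backfit"))
  structure(list(mu = mu, sigma = sigma, n_used = as.integer(n_used),
                 source = source, inlier_ids = inlier_ids),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Null model (%s): mu = %.5g, sigma = %.5g, n = %d\n",
              x$source, x$mu, x$sigma, x$n_used))
  invisible(x)
}

#' Back-derive a null model from paired statistic and Z-score values
#'
#' Published screen hit tables report, per clone, both the raw statistic
#' (delta V or log10 expression ratio) and its Z-score, but not the null
#' parameters used to standardize. Because `z = (x - mu)/sigma` is affine in
#' `x`, an ordinary least-squares fit of printed Z on printed statistic
#' recovers `sigma` as the inverse slope and `mu` as `-intercept/slope`. With
#' exact table values the fit is essentially perfect; residuals are limited
#' only by the rounding of the printed statistic.
#'
#' @param x Numeric vector of the raw statistic values (e.g. delta V as a
#'   fraction).
#' @param z Numeric vector of the corresponding Z-scores.
#' @return A list with the recovered [new_null_model()] in `$null`, the fitted
#'   `lm` object in `$fit`, and the per-row residuals (Z units) in
#'   `$residuals`.
#' @examples
#' tab <- viability_hit_table()
#' low <- tab[tab$dose == 0.5, ]
#' implied_null(low$delta_v, low$z)$null
#' @export
implied_null <- function(x, z) {
  stopifnot(length(x) == length(z), length(x) >= 2)
  fit <- stats::lm(z ~ x)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope == 0) {
    ts_error("degenerate_null_error", "statistic does not predict Z (zero slope)")
  }
  sigma <- 1 / slope
  mu <- -coef(fit)[[1]] / slope
  list(null = new_null_model(mu, abs(sigma), length(x), "table_backfit"),
       fit = fit, residuals = unname(resid(fit)))
}
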