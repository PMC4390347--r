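test_that("percent viability is the live fraction of the total signal", {
  expect_equal(percent_viability(0, 1000), 1.0)
  expect_equal(percent_viability(400, 1000), 0.6)
  expect_equal(percent_viability(1000, 1000), 0.0)
  expect_error(percent_viability(10, 0), class = "undefined_well_error")
  expect_error(percent_viability(1200, 1000), class = "qc_error")
})

test_that("delta viability is a signed difference of fractions", {
  expect_equal(delta_viability(0.6, 0.6), 0)
  expect_equal(delta_viability(0.29, 0.60), -0.31)
  expect_equal(delta_viability(0.9977, 0.6), 0.3977)
})

test_that("wild-type null uses sample mean and n-1 SD, rejecting degenerate input", {
  expect_error(fit_wt_null(c(-0.01, -0.01)), class = "degenerate_null_error")
  expect_error(fit_wt_null(0.3), class = "insufficient_null_error")
  m <- fit_wt_null(c(0, 0.02))
  expect_equal(m$mu, 0.01)
  expect_equal(m$sigma, sqrt(2e-4), tolerance = 1e-10)
  expect_equal(m$source, "wt_replicates")

  # sampling-distribution check: 22 draws recover the generating mean
  set.seed(42)
  draws <- rnorm(22, -0.027, 0.080)
  fit <- fit_wt_null(draws)
  expect_lt(abs(fit$mu - (-0.027)), 3 * 0.080 / sqrt(22))
})

test_that("Z-scores are centred, scaled, and affine equivariant", {
  null <- new_null_model(-0.02, 0.07, 22, "wt_replicates")
  expect_equal(z_score(-0.02, null), 0)
  set.seed(7)
  dv <- rnorm(50, 0, 0.07)
  wt <- rnorm(22, -0.02, 0.07)
  z0 <- z_score(dv, fit_wt_null(wt))
  for (tr in list(c(add = 0.13, mul = 1), c(add = 0, mul = 3.7),
                  c(add = -0.05, mul = 0.4))) {
    z1 <- z_score(dv * tr[["mul"]] + tr[["add"]],
                  fit_wt_null(wt * tr[["mul"]] + tr[["add"]]))
    expect_equal(z1, z0, tolerance = 1e-12)
  }
})

test_that("two-tailed p is symmetric, monotone, and never underflows to zero", {
  expect_equal(two_tailed_p(0), 1)
  zs <- c(0.3, 1.1, 2.5, 4.4, 6.5, 8, 12, 20, 38)
  expect_equal(two_tailed_p(zs), two_tailed_p(-zs))
  expect_true(all(diff(two_tailed_p(zs)) < 0))
  expect_gt(two_tailed_p(40), 0)
  # log-scale variant stays exact far beyond double underflow
  expect_equal(log10_two_tailed_p(4.41953), log10(two_tailed_p(4.41953)),
               tolerance = 1e-12)
  expect_lt(log10_two_tailed_p(50), -500)
})

test_that("duplicate averaging commutes with the viability pipeline", {
  sim <- simulate_screen(synthetic_screen_config(n_clones = 30, seed = 5))
  res <- viability_results(sim$dataset)

  # collapse duplicates to their mean viability, rebuild a 1-replicate dataset
  rec <- sim$dataset$records
  v <- percent_viability(rec$dead_rlu, rec$total_rlu)
  key <- interaction(rec$clone_id, rec$dose_gy, drop = TRUE)
  first <- !duplicated(key)
  collapsed <- rec[first, ]
  vbar <- as.numeric(tapply(v, key, mean)[as.character(key[first])])
  collapsed$replicate <- 1L
  collapsed$total_rlu <- 1000
  collapsed$dead_rlu <- (1 - vbar) * 1000
  collapsed$betagal_rlu <- ifelse(collapsed$is_wildtype, NA_real_, 1)
  res2 <- viability_results(screen_dataset(collapsed))

  ord <- order(res$clone_id, res$dose_gy)
  ord2 <- order(res2$clone_id, res2$dose_gy)
  expect_equal(res2$delta_v[ord2], res$delta_v[ord], tolerance = 1e-12)
  expect_equal(res2$z[ord2], res$z[ord], tolerance = 1e-9)
})

test_that("hit partitioning handles edge cases", {
  tab <- viability_hit_table()
  expect_equal(call_viability_hits(tab, alpha = 0)$n_unique, 0L)
  empty <- tab[0, ]
  calls <- call_viability_hits(empty)
  expect_length(calls$partitions, 0L)
  expect_equal(calls$n_unique, 0L)
})

test_that("direction reflects deviation from the wild-type drift", {
  # a clone moving exactly with the WT mean (negative drift) is not 'decreased'
  sim <- simulate_screen(synthetic_screen_config(n_clones = 40, seed = 9))
  res <- viability_results(sim$dataset)
  nulls <- attr(res, "nulls")
  for (d in names(nulls)) {
    sub <- res[res$dose_gy == as.numeric(d), ]
    expect_equal(sub$direction == "increased",
                 sub$delta_v > nulls[[d]]$mu)
  }
})

test_that("viability type-I error matches the exact small-null-sample prediction", {
  # With the null mean/SD estimated from n WT replicates and normal-quantile
  # p-values, the exact null hit rate at alpha is
  # 2 * pt(-z_{alpha/2} / sqrt(1 + 1/n), n - 1), ~0.020 at alpha = 0.01, n = 22.
  n_wt <- 22
  predicted <- 2 * pt(qnorm(0.005) / sqrt(1 + 1 / n_wt), n_wt - 1)
  rates <- vapply(1:30, function(r) {
    sim <- simulate_screen(synthetic_screen_config(
      n_clones = 60, n_wt_replicates = n_wt, doses = c(0, 4), seed = 1000 + r))
    mean(viability_results(sim$dataset)$p < 0.01)
  }, numeric(1))
  expect_equal(mean(rates), predicted, tolerance = 0.35)
  # and it is genuinely inflated relative to the nominal alpha
  expect_gt(mean(rates), 0.01)
})
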