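test_that("beta-gal normalization divides by the live-cell signal", {
  expect_equal(betagal_per_live(600, 600), 1.0)
  expect_equal(betagal_per_live(900, 600), 1.5)
  expect_error(betagal_per_live(100, 0), class = "dead_well_error")
})

test_that("dose log-ratios are base 10 and antisymmetric", {
  expect_equal(log10_dose_ratio(2, 2), 0)
  expect_equal(log10_dose_ratio(2.76, 1), 0.44, tolerance = 0.005)
  expect_equal(log10_dose_ratio(1, 2), -0.30103, tolerance = 1e-5)
  set.seed(3)
  a <- runif(20, 0.1, 5); b <- runif(20, 0.1, 5)
  expect_equal(log10_dose_ratio(a, b), -log10_dose_ratio(b, a))
  expect_error(log10_dose_ratio(-1, 2), class = "domain_error")
})

test_that("signed fold change follows the display convention", {
  expect_equal(signed_fold_change(c(2.76, 1, 0.5)), c(2.76, 1, -2))
  expect_error(signed_fold_change(0), class = "domain_error")
})

test_that("RANSAC null recovers moments on clean data", {
  errs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    x <- rnorm(400, 0, 0.3)
    fit <- ransac_null(x, ransac_config(seed = s))
    c(mu = abs(fit$mu), dsig = abs(fit$sigma - 0.3),
      dmu = abs(fit$mu - mean(x)), dsd = abs(fit$sigma - sd(x)))
  })
  expect_true(all(errs["mu", ] < 0.05))
  expect_true(all(errs["dsig", ] < 0.05))
  expect_lt(mean(errs["dmu", ]), 0.02)
  expect_lt(mean(errs["dsd", ]), 0.02)
})

test_that("RANSAC null resists contamination that shifts the naive mean", {
  set.seed(9)
  x <- c(rnorm(360, 0, 0.3), rnorm(40, 1.5, 0.3))
  fit <- ransac_null(x, ransac_config(seed = 2))
  expect_lt(abs(fit$mu), 0.05)
  expect_gt(abs(naive_location(x)), 0.10)
  # inliers exclude most of the contaminated block
  expect_lt(mean(seq(361, 400) %in% fit$inlier_ids), 0.5)
})

test_that("RANSAC null is scale equivariant at fixed seed", {
  set.seed(21)
  x <- c(rnorm(300, 0, 0.2), rnorm(30, 1.2, 0.2))
  f1 <- ransac_null(x, ransac_config(seed = 4))
  k <- 3.5
  f2 <- ransac_null(k * x, ransac_config(seed = 4))
  expect_equal(f2$mu, k * f1$mu, tolerance = 1e-9)
  expect_equal(f2$sigma, k * f1$sigma, tolerance = 1e-9)
  expect_equal(z_score(k * x, f2), z_score(x, f1), tolerance = 1e-9)
})

test_that("RANSAC null rejects unusable input", {
  expect_error(ransac_null(1), class = "insufficient_data_error")
  expect_error(ransac_null(rep(0.2, 50)), class = "degenerate_null_error")
  # a 60/40 two-mode split cannot reach a 75% consensus
  x <- c(rnorm(60, 0, 0.05), rnorm(40, 5, 0.05))
  expect_error(
    ransac_null(x, ransac_config(min_consensus_fraction = 0.75, seed = 1)),
    class = "robust_fit_failure")
})

test_that("expression scoring matches the shared Z/p machinery", {
  null <- new_null_model(0.01, 0.2, 300, "ransac_consensus")
  rows <- data.frame(clone_id = c("a", "b"), gene_symbol = c("A", "B"),
                     log10_ratio = c(0.01, 0.91))
  scored <- expression_z_and_p(rows, null)
  expect_equal(scored$z[1], 0)
  expect_equal(scored$p[1], 1)
  expect_equal(scored$z[2], 4.5)
  expect_equal(scored$direction, c("decreased", "increased"))
  expect_true(scored$is_hit[2] && !scored$is_hit[1])
})

test_that("published expression rows imply per-dose null scales near 0.14 and 0.19", {
  tab <- expression_hit_table()
  for (d in c(0.5, 4)) {
    sub <- tab[tab$dose_gy == d, ]
    fit <- implied_null(sub$log10_ratio, sub$z)
    expect_lt(max(abs(fit$residuals)), 0.1)
    if (d == 0.5) expect_equal(fit$null$sigma, 0.14, tolerance = 0.015)
    if (d == 4) expect_equal(fit$null$sigma, 0.19, tolerance = 0.02)
  }
})

test_that("cross-dose overlap is a plain set intersection", {
  calls <- call_expression_hits(expression_hit_table())
  low <- unique(unlist(calls$partitions[grep("^0.5:", names(calls$partitions))]))
  high <- unique(unlist(calls$partitions[grep("^4:", names(calls$partitions))]))
  expect_setequal(cross_dose_overlap(low, high), c("Brcc3", "Dstn", "Pex14"))
  expect_length(cross_dose_overlap("A", "B"), 0L)
  expect_equal(cross_dose_overlap(c("A", "B"), c("B", "A")), c("A", "B"))
})

test_that("dead wells are excluded from expression analysis with a message", {
  sim <- simulate_screen(synthetic_screen_config(n_clones = 15, seed = 13))
  rec <- sim$dataset$records
  kill <- which(!rec$is_wildtype & rec$dose_gy == 4)[1]
  rec$dead_rlu[kill] <- rec$total_rlu[kill]        # live signal 0
  ds <- screen_dataset(rec)
  expect_message(res <- expression_results(ds), "non-positive live")
  expect_false(rec$clone_id[kill] %in% res$clone_id)
})
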