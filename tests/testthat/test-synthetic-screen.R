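test_that("the generator is deterministic and structurally complete", {
  cfg <- synthetic_screen_config(n_clones = 25, seed = 77)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth, b$truth)

  rec <- a$dataset$records
  # every clone x dose x duplicate cell is present
  expect_equal(nrow(rec), (25 + 22) * 3 * 2)
  expect_equal(length(a$dataset$background_genes), 25)
  expect_true(all(is.na(rec$betagal_rlu[rec$is_wildtype])))
  expect_true(all(rec$dead_rlu <= rec$total_rlu))
})

test_that("planted genes must exist and invalid configs are rejected", {
  expect_error(
    synthetic_screen_config(n_clones = 5, planted_hits = data.frame(
      gene = "G0099", dose = 4, dv_effect = -0.3)),
    class = "config_error")
  expect_error(synthetic_screen_config(doses = c(0.5, 4)),
               class = "config_error")
  expect_error(synthetic_screen_config(wt_dv_sd = 0.01,
                                       viability_well_sd = 0.046),
               class = "config_error")
})

test_that("observable wild-type delta-V converges to the configured null", {
  cfg <- synthetic_screen_config(n_clones = 2, n_wt_replicates = 10000,
                                 seed = 31)
  sim <- simulate_screen(cfg)
  res_wt <- local({
    rec <- sim$dataset$records[sim$dataset$records$is_wildtype, ]
    v <- percent_viability(rec$dead_rlu, rec$total_rlu)
    key <- paste(rec$clone_id, rec$dose_gy)
    vbar <- tapply(v, key, mean)
    ids <- unique(rec$clone_id)
    sapply(c("0.5", "4"), function(d) {
      vbar[paste(ids, d)] - vbar[paste(ids, "0")]
    })
  })
  n <- nrow(res_wt)
  for (d in c("0.5", "4")) {
    mu <- cfg$wt_dv_mean[[d]]; sg <- cfg$wt_dv_sd[[d]]
    expect_lt(abs(mean(res_wt[, d]) - mu), 3 * sg / sqrt(n))
    expect_lt(abs(sd(res_wt[, d]) - sg), 3 * sg / sqrt(2 * n))
  }
})

test_that("observable null log10 expression ratios converge to the configured SD", {
  cfg <- synthetic_screen_config(n_clones = 5000, n_wt_replicates = 2,
                                 doses = c(0, 4), seed = 57)
  sim <- simulate_screen(cfg)
  rec <- sim$dataset$records[!sim$dataset$records$is_wildtype, ]
  live <- rec$total_rlu - rec$dead_rlu
  e <- betagal_per_live(rec$betagal_rlu, live)
  key <- paste(rec$clone_id, rec$dose_gy)
  ebar <- tapply(e, key, mean)
  ids <- unique(rec$clone_id)
  lr <- log10(ebar[paste(ids, "4")] / ebar[paste(ids, "0")])
  n <- length(lr)
  expect_lt(abs(mean(lr)), 3 * 0.2 / sqrt(n))
  expect_lt(abs(sd(lr) - 0.2), 3 * 0.2 / sqrt(2 * n))
})

test_that("larger planted effects yield larger expected |Z| downstream", {
  effects <- c(0.1, 0.2, 0.3)
  mean_abs_z <- sapply(effects, function(eff) {
    zs <- sapply(1:4, function(r) {
      cfg <- synthetic_screen_config(
        n_clones = 40, doses = c(0, 4), seed = 300 + r,
        planted_hits = data.frame(gene = "G0001", dose = 4,
                                  dv_effect = -eff, expr_effect = eff))
      sim <- simulate_screen(cfg)
      vr <- viability_results(sim$dataset)
      er <- expression_results(sim$dataset)
      c(abs(vr$z[vr$gene_symbol == "G0001"]),
        abs(er$z[er$gene_symbol == "G0001"]))
    })
    mean(zs)
  })
  expect_true(all(diff(mean_abs_z) > 0))
})

test_that("fixtures round-trip through disk and regenerate identically", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_screen_config(
    n_clones = 12, seed = 19,
    planted_hits = data.frame(gene = "G0003", dose = 4, dv_effect = -0.3,
                              expr_effect = 0))
  paths <- emit_fixture(cfg, dir)
  expect_true(all(file.exists(paths)))

  ds <- read_plate_table(paths[["plate_table"]])
  expect_equal(length(ds$background_genes), 12)

  cfg2 <- read_screen_config(paths[["config"]])
  dir2 <- withr::local_tempdir()
  paths2 <- emit_fixture(cfg2, dir2)
  expect_identical(readLines(paths[["plate_table"]]),
                   readLines(paths2[["plate_table"]]))
  expect_identical(readLines(paths[["ground_truth"]]),
                   readLines(paths2[["ground_truth"]]))
})

test_that("a zero-clone config emits a header-only plate table", {
  dir <- withr::local_tempdir()
  paths <- emit_fixture(synthetic_screen_config(n_clones = 0, seed = 1), dir)
  expect_equal(length(readLines(paths[["plate_table"]])), 1L)
})
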