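#' Configuration for the synthetic screen generator
#'
#' The generator emulates the statistical structure of a dual-assay gene-trap
#' ESC irradiation screen: ~386 assayed clones plus ~22 wild-type replicate
#' wells, duplicate measurements, doses 0/0.5/4 Gy, a wild-type
#' delta-viability null of a few percent loss with SD 7-8%, a beta-gal
#' log10-ratio null centred at 0, and planted hits at stated effect sizes.
#'
#' `wt_dv_mean` / `wt_dv_sd` are the mean and SD of the *observable*
#' duplicate-averaged wild-type delta viability per positive dose (the
#' quantities the wild-type null estimates downstream). The defaults are
#' back-derived from published hit tables via [implied_null()]. Likewise
#' `expr_log10_sd` is the observable SD of the null log10 expression ratio.
#' Well-level noise (`viability_well_sd`, on the viability fraction;
#' `expr_well_log10_sd`, on log10 expression) sets duplicate concordance; the
#' clone-level variance components are derived internally by subtraction, so
#' the observable SDs match the configured values exactly in expectation.
#' `measurement_cv` is multiplicative lognormal noise on raw RLU magnitudes;
#' it cancels in the normalized ratios the pipeline consumes and only shapes
#' the raw luminescence scale.
#'
#' @param n_clones Number of mutant clones (default 386).
#' @param n_wt_replicates Number of wild-type replicate wells (default 22).
#' @param doses Dose set in Gy, must include 0 (default 0, 0.5, 4).
#' @param n_duplicates Duplicate wells per clone per dose (default 2).
#' @param wt_dv_mean Named numeric, mean wild-type delta viability per
#'   positive dose (fractions; defaults -0.0149 at 0.5 Gy, -0.0272 at 4 Gy).
#' @param wt_dv_sd Named numeric, SD of wild-type delta viability per positive
#'   dose (defaults 0.0665 at 0.5 Gy, 0.0800 at 4 Gy).
#' @param base_viability Mean 0-Gy viability fraction (default 0.6).
#' @param rlu_scale Mean total-cell RLU per well (default 1e4).
#' @param measurement_cv Coefficient of variation of the lognormal RLU
#'   magnitude noise (default 0.06).
#' @param viability_well_sd Well-level Gaussian SD on the viability fraction
#'   (default 0.046; sets viability duplicate concordance ~0.7).
#' @param expr_log10_sd Named numeric, observable SD of the null log10
#'   expression ratio per positive dose (defaults 0.14 at 0.5 Gy, 0.20 at
#'   4 Gy, matching the scales implied by published expression hit tables).
#' @param expr_well_log10_sd Well-level Gaussian SD on log10 expression
#'   (default 0.028; sets beta-gal duplicate concordance >0.95).
#' @param planted_hits `NULL`, or a data frame with columns `gene`, `dose`,
#'   and effect columns `dv_effect` (additive on the viability fraction)
#'   and/or `expr_effect` (additive on log10 expression). Planted genes must
#'   be among the generated genes (`"G0001"`, `"G0002"`, ...).
#' @param clones_per_gene Clones generated per gene (default 1, mirroring
#'   top-clone-per-gene screen designs).
#' @param seed Integer seed; all draws derive from it via fixed substream
#'   offsets, so regenerating with the same config is byte-identical.
#' @return A list of class `synthetic_screen_config`.
#' @seealso [simulate_screen()], [emit_fixture()]
#' @export
synthetic_screen_config <- function(n_clones = 386,
                                    n_wt_replicates = 22,
                                    doses = c(0, 0.5, 4),
                                    n_duplicates = 2,
                                    wt_dv_mean = c("0.5" = -0.0149, "4" = -0.0272),
                                    wt_dv_sd = c("0.5" = 0.0665, "4" = 0.0800),
                                    base_viability = 0.6,
                                    rlu_scale = 1e4,
                                    measurement_cv = 0.06,
                                    viability_well_sd = 0.046,
                                    expr_log10_sd = c("0.5" = 0.14, "4" = 0.20),
                                    expr_well_log10_sd = 0.028,
                                    planted_hits = NULL,
                                    clones_per_gene = 1,
                                    seed = 1L) {
  doses <- sort(unique(as.numeric(doses)))
  if (!0 %in% doses || length(doses) < 2) {
    ts_error("config_error", "doses must include 0 and at least one positive dose")
  }
  pos <- setdiff(doses, 0)
  wt_dv_mean <- expand_per_dose(wt_dv_mean, pos, "wt_dv_mean")
  wt_dv_sd <- expand_per_dose(wt_dv_sd, pos, "wt_dv_sd")
  expr_log10_sd <- expand_per_dose(expr_log10_sd, pos, "expr_log10_sd")
  stopifnot(n_clones >= 0, n_wt_replicates >= 0, n_duplicates >= 1,
            base_viability > 0, base_viability < 1,
            rlu_scale > 0, measurement_cv >= 0, viability_well_sd >= 0,
            expr_well_log10_sd >= 0, clones_per_gene >= 1)
  if (any(wt_dv_sd <= 0) || any(expr_log10_sd <= 0)) {
    ts_error("config_error", "null SDs must be positive")
  }
  # Observable delta-V variance = clone-level + well-level (duplicate-averaged
  # well noise contributes viability_well_sd^2 * (1/dup + 1/dup) ... with the
  # dose and reference means each averaged over n_duplicates wells.
  well_var_dv <- 2 * viability_well_sd^2 / n_duplicates
  if (any(wt_dv_sd^2 <= well_var_dv)) {
    ts_error("config_error",
             "wt_dv_sd too small for the configured viability_well_sd")
  }
  well_var_lr <- 2 * expr_well_log10_sd^2 / n_duplicates
  if (any(expr_log10_sd^2 <= well_var_lr)) {
    ts_error("config_error",
             "expr_log10_sd too small for the configured expr_well_log10_sd")
  }
  if (!is.null(planted_hits)) {
    planted_hits <- as.data.frame(planted_hits)
    if (!all(c("gene", "dose") %in% names(planted_hits))) {
      ts_error("config_error", "planted_hits needs columns gene, dose")
    }
    if (!"dv_effect" %in% names(planted_hits)) planted_hits$dv_effect <- 0
    if (!"expr_effect" %in% names(planted_hits)) planted_hits$expr_effect <- 0
    genes <- gene_names(n_clones)
    unknown <- setdiff(planted_hits$gene, genes)
    if (length(unknown) > 0) {
      ts_error("config_error",
               paste("planted gene(s) not among generated genes:",
                     paste(head(unknown, 5), collapse = ", ")))
    }
    if (!all(planted_hits$dose %in% pos)) {
      ts_error("config_error", "planted_hits doses must be positive screen doses")
    }
  }
  structure(list(n_clones = as.integer(n_clones),
                 n_wt_replicates = as.integer(n_wt_replicates),
                 doses = doses, n_duplicates = as.integer(n_duplicates),
                 wt_dv_mean = wt_dv_mean, wt_dv_sd = wt_dv_sd,
                 base_viability = base_viability, rlu_scale = rlu_scale,
                 measurement_cv = measurement_cv,
                 viability_well_sd = viability_well_sd,
                 expr_log10_sd = expr_log10_sd,
                 expr_well_log10_sd = expr_well_log10_sd,
                 planted_hits = planted_hits,
                 clones_per_gene = as.integer(clones_per_gene),
                 seed = as.integer(seed)),
            class = "synthetic_screen_config")
}

expand_per_dose <- function(x, pos_doses, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(setNames(rep(as.numeric(x), length(pos_doses)),
                    as.character(pos_doses)))
  }
  key <- as.character(pos_doses)
  if (!all(key %in% names(x))) {
    # unnamed vector of matching length is taken in dose order
    if (is.null(names(x)) && length(x) == length(pos_doses)) {
      return(setNames(as.numeric(x), key))
    }
    ts_error("config_error",
             sprintf("%s must name every positive dose (%s)", what,
                     paste(key, collapse = ", ")))
  }
  setNames(as.numeric(x[key]), key)
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))

# mean-1 lognormal multiplier with coefficient of variation cv
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate a dual-assay gene-trap screen
#'
#' Generates well-level records with the structure the analysis assumes. Per
#' clone and positive dose, a clone-level delta-viability draw (wild-type null
#' mean/SD plus any planted effect) is shared across duplicates; independent
#' Gaussian well noise is added on the viability fraction, and the result is
#' clipped to `[0.02, 0.98]` (clipping counted in the `clipped` attribute).
#' Expression per clone and dose follows `10^(null draw + planted effect)`
#' relative to 0 Gy, with Gaussian well noise on the log10 scale; beta-gal
#' RLU is the live-cell RLU times the expression level. Raw RLU magnitudes
#' carry multiplicative lognormal noise of CV `measurement_cv`. All draws are
#' governed by the config seed through fixed substream offsets, so identical
#' configs give byte-identical output.
#'
#' @param config A [synthetic_screen_config()].
#' @return A list with `dataset` (a [screen_dataset()]) and `truth` (a data
#'   frame of per-gene, per-dose true effects and hit labels). The number of
#'   clipped viability values is attached to `dataset` as attribute
#'   `"clipped"`.
#' @examples
#' sim <- simulate_screen(synthetic_screen_config(n_clones = 20, seed = 7))
#' sim$dataset
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  pos <- setdiff(config$doses, 0)
  n_dup <- config$n_duplicates

  if (config$n_clones == 0) {
    empty <- data.frame(clone_id = character(), gene_symbol = character(),
                        dose_gy = numeric(), replicate = integer(),
                        dead_rlu = numeric(), total_rlu = numeric(),
                        betagal_rlu = numeric(), is_wildtype = logical())
    ds <- screen_dataset(empty, dose_set = config$doses)
    truth <- data.frame(gene = character(), dose = numeric(),
                        dv_effect = numeric(), expr_effect = numeric(),
                        is_dv_hit = logical(), is_expr_hit = logical())
    return(list(dataset = ds, truth = truth))
  }

  genes <- gene_names(config$n_clones)
  clone_gene <- rep(genes, each = config$clones_per_gene)
  clone_id <- if (config$clones_per_gene == 1) clone_gene else {
    paste0(clone_gene, "_c", sequence(rep(config$clones_per_gene,
                                          length(genes))))
  }
  n_cl <- length(clone_id)
  wt_id <- sprintf("WT%02d", seq_len(config$n_wt_replicates))
  units <- c(clone_id, wt_id)            # each unit behaves like one sample
  unit_gene <- c(clone_gene, rep("WT", length(wt_id)))
  unit_wt <- c(rep(FALSE, n_cl), rep(TRUE, length(wt_id)))
  n_units <- length(units)

  # planted effect lookup per gene x dose
  effect <- function(gene, dose, col) {
    ph <- config$planted_hits
    if (is.null(ph)) return(numeric(length(gene)) * 0)
    out <- numeric(length(gene))
    sel <- ph$dose == dose
    if (any(sel)) {
      m <- match(gene, ph$gene[sel])
      hit <- !is.na(m)
      out[hit] <- ph[[col]][sel][m[hit]]
    }
    out
  }

  # clone-level variance components (observable SD minus well-noise share)
  well_var_dv <- 2 * config$viability_well_sd^2 / n_dup
  well_var_lr <- 2 * config$expr_well_log10_sd^2 / n_dup

  # --- clone-level draws (substreams: 1 viability, 2 expression) ---
  dv_clone <- with_local_seed(substream_seed(config$seed, 1), {
    sapply(as.character(pos), function(d) {
      sd_c <- sqrt(config$wt_dv_sd[[d]]^2 - well_var_dv)
      mu <- config$wt_dv_mean[[d]] +
        ifelse(unit_wt, 0, effect(unit_gene, as.numeric(d), "dv_effect"))
      stats::rnorm(n_units, mu, sd_c)
    })
  })
  dv_clone <- matrix(dv_clone, nrow = n_units,
                     dimnames = list(units, as.character(pos)))
  lr_clone <- with_local_seed(substream_seed(config$seed, 2), {
    sapply(as.character(pos), function(d) {
      sd_c <- sqrt(config$expr_log10_sd[[d]]^2 - well_var_lr)
      mu <- ifelse(unit_wt, 0, effect(unit_gene, as.numeric(d), "expr_effect"))
      stats::rnorm(n_units, mu, sd_c)
    })
  })
  lr_clone <- matrix(lr_clone, nrow = n_units,
                     dimnames = list(units, as.character(pos)))

  # --- well-level assembly (substream 3: well noise; 4: RLU magnitudes) ---
  grid <- expand.grid(replicate = seq_len(n_dup), dose_gy = config$doses,
                      unit = seq_len(n_units), KEEP.OUT.ATTRS = FALSE)
  n_wells <- nrow(grid)
  dmatch <- match(as.character(grid$dose_gy), as.character(pos))  # NA for 0 Gy
  dv_well_mean <- ifelse(is.na(dmatch), 0,
                         dv_clone[cbind(grid$unit, dmatch)])
  lr_well_mean <- ifelse(is.na(dmatch), 0,
                         lr_clone[cbind(grid$unit, dmatch)])

  noise <- with_local_seed(substream_seed(config$seed, 3), {
    list(v = stats::rnorm(n_wells, 0, config$viability_well_sd),
         e = stats::rnorm(n_wells, 0, config$expr_well_log10_sd))
  })
  v_well <- config$base_viability + dv_well_mean + noise$v
  clipped <- sum(v_well < 0.02 | v_well > 0.98)
  if (clipped > 0) {
    message(sprintf("clipping %d well viability value(s) to [0.02, 0.98]",
                    clipped))
  }
  v_well <- pmin(pmax(v_well, 0.02), 0.98)
  expr_well <- 10^(lr_well_mean + noise$e)

  mags <- with_local_seed(substream_seed(config$seed, 4), {
    lognoise(n_wells, config$measurement_cv)
  })
  total <- config$rlu_scale * mags
  dead <- (1 - v_well) * total
  live <- total - dead
  betagal <- ifelse(unit_wt[grid$unit], NA_real_, live * expr_well)

  records <- data.frame(
    clone_id = units[grid$unit],
    gene_symbol = unit_gene[grid$unit],
    dose_gy = grid$dose_gy,
    replicate = grid$replicate,
    dead_rlu = dead,
    total_rlu = total,
    betagal_rlu = betagal,
    is_wildtype = unit_wt[grid$unit],
    stringsAsFactors = FALSE
  )
  ds <- screen_dataset(records, dose_set = config$doses)
  attr(ds, "clipped") <- clipped

  truth <- expand.grid(gene = genes, dose = pos, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  truth$dv_effect <- effect(truth$gene, 0, "dv_effect") * 0
  truth$expr_effect <- truth$dv_effect
  for (d in pos) {
    sel <- truth$dose == d
    truth$dv_effect[sel] <- effect(truth$gene[sel], d, "dv_effect")
    truth$expr_effect[sel] <- effect(truth$gene[sel], d, "expr_effect")
  }
  truth$is_dv_hit <- truth$dv_effect != 0
  truth$is_expr_hit <- truth$expr_effect != 0

  list(dataset = ds, truth = truth)
}

#' Write a synthetic screen to disk as plain-text fixtures
#'
#' Writes the plate table (TSV), the ground-truth table (TSV) and a JSON
#' snapshot of the configuration. Regenerating from the snapshot reproduces
#' the files exactly.
#'
#' @param config A [synthetic_screen_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
emit_fixture <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) ts_error("io_error", paste("cannot create", dir))
  sim <- simulate_screen(config)
  paths <- c(plate_table = file.path(dir, "plate_table.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"),
             config = file.path(dir, "config.json"))
  write_plate_table(sim$dataset, paths[["plate_table"]])
  utils::write.table(sim$truth, paths[["ground_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths
}

#' Restore a generator configuration from a JSON snapshot
#'
#' @param path Path to a `config.json` written by [emit_fixture()].
#' @return A [synthetic_screen_config()].
#' @export
read_screen_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted <- cfg$planted_hits
  if (!is.null(planted) && length(planted) == 0) planted <- NULL
  synthetic_screen_config(
    n_clones = cfg$n_clones, n_wt_replicates = cfg$n_wt_replicates,
    doses = cfg$doses, n_duplicates = cfg$n_duplicates,
    wt_dv_mean = unlist(cfg$wt_dv_mean), wt_dv_sd = unlist(cfg$wt_dv_sd),
    base_viability = cfg$base_viability, rlu_scale = cfg$rlu_scale,
    measurement_cv = cfg$measurement_cv,
    viability_well_sd = cfg$viability_well_sd,
    expr_log10_sd = unlist(cfg$expr_log10_sd),
    expr_well_log10_sd = cfg$expr_well_log10_sd,
    planted_hits = planted, clones_per_gene = cfg$clones_per_gene,
    seed = cfg$seed)
}
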