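#' Configuration of an end-to-end simulated study
#'
#' Bundles the cohort, protocol, noise and analysis settings of a full
#' run: simulate -> calibrate -> analyze -> compare. All stochastic
#' stages derive their streams from `seed`.
#'
#' @param scenario `"vsmc"` or `"vec"`.
#' @param condition protocol template (`"co2_dma"`, `"co2"`, `"free"`).
#' @param n_risk,n_protective cells per genotype group.
#' @param jitter_cv per-cell parameter jitter CV.
#' @param noise_cv photometric noise CV.
#' @param window_s uptake regression window, seconds.
#' @param bin_width uptake pH bin width.
#' @param grid_start_s,grid_end_s,grid_step_s recovery-window grid.
#' @param seed integer seed (mandatory).
#' @return A list of class `phiflux_config`.
#' @export
run_config <- function(scenario = "vsmc", condition = "co2_dma",
                       n_risk = 5, n_protective = 7, jitter_cv = 0.03,
                       noise_cv = 0.005, window_s = 15, bin_width = 0.05,
                       grid_start_s = 60, grid_end_s = 900,
                       grid_step_s = 3, seed = 1) {
  cfg <- list(scenario = match.arg(scenario, c("vsmc", "vec")),
              condition = match.arg(condition,
                                    c("co2_dma", "co2", "free")),
              n_risk = as.integer(n_risk),
              n_protective = as.integer(n_protective),
              jitter_cv = jitter_cv, noise_cv = noise_cv,
              window_s = window_s, bin_width = bin_width,
              grid_start_s = grid_start_s, grid_end_s = grid_end_s,
              grid_step_s = grid_step_s, seed = as.integer(seed))
  structure(cfg, class = "phiflux_config")
}

#' Read a run configuration from a flat key = value text file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Unknown keys are an error. Values are coerced to the type of
#' the corresponding [run_config()] default.
#'
#' @param path configuration file path.
#' @return A `phiflux_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("format error: ", path, ": file not found", call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- formals(run_config)
  args <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("format error: ", path, ": '", lines[i],
           "' is not 'key = value'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults))
      stop("format error: ", path, ": unknown key '", key, "'",
           call. = FALSE)
    args[[key]] <- if (key %in% c("scenario", "condition")) val
                   else as.numeric(val)
  }
  do.call(run_config, args)
}

#' Analyze a set of recorded traces
#'
#' Runs [analyze_cell()] on every trace and assembles the per-cell
#' results table, pooled per-group uptake estimates and the
#' recovery-window matrix.
#'
#' @param traces named list of [fluorescence_trace()]s.
#' @param genotype character vector parallel to `traces` (`risk` /
#'   `protective`); defaults to the prefix of each trace name.
#' @param condition condition label recorded in the results table.
#' @inheritParams analyze_cell
#' @return A list: `cells` (data.frame with beta, plateau and baseline
#'   pH per cell), `estimates` (pooled per-window uptake estimates with
#'   genotype), `profiles` (per-genotype binned uptake), `recovery`
#'   (cells x grid matrix) and `analyses` (raw per-cell results).
#' @export
analyze_cohort <- function(traces, genotype = NULL,
                           condition = "co2_dma", window_s = 15,
                           bin_width = 0.05,
                           grid = list(start_s = 60, end_s = 900,
                                       step_s = 3)) {
  stopifnot(is.list(traces), length(traces) >= 1)
  ids <- names(traces) %||% sprintf("cell_%02d", seq_along(traces))
  genotype <- genotype %||% sub("_.*$", "", ids)
  analyses <- vector("list", length(traces))
  cells <- vector("list", length(traces))
  est <- vector("list", length(traces))
  recov <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    an <- tryCatch(
      analyze_cell(traces[[i]], window_s, bin_width, grid),
      error = function(e) stop("stage 'analyze', cell '", ids[i], "': ",
                               conditionMessage(e), call. = FALSE))
    analyses[[i]] <- an
    cells[[i]] <- data.frame(cell_id = ids[i], condition = condition,
                             genotype = genotype[i],
                             beta = an$buffering$beta,
                             plateau_ph = an$plateau$plateau_ph,
                             baseline_ph = an$plateau$baseline_ph)
    e <- an$uptake$estimates
    e$cell_id <- ids[i]
    e$genotype <- genotype[i]
    est[[i]] <- e
    recov[[i]] <- an$recovery
  }
  est <- do.call(rbind, est)
  profiles <- do.call(rbind, lapply(split(est, est$genotype), function(g) {
    centre <- (floor(g$mean_ph / bin_width) + 0.5) * bin_width
    pr <- stats::aggregate(g$uptake, list(bin_center = centre), mean)
    names(pr)[2] <- "uptake"
    pr$n <- as.vector(table(centre)[as.character(pr$bin_center)])
    pr$genotype <- g$genotype[1]
    pr
  }))
  rownames(profiles) <- NULL
  recovery <- do.call(rbind, recov)
  rownames(recovery) <- ids
  list(cells = do.call(rbind, cells), estimates = est,
       profiles = profiles, recovery = recovery, analyses = analyses)
}

#' Run the full simulated-study pipeline
#'
#' Simulates a genotype cohort, calibrates and converts every recording,
#' computes the per-cell derived quantities, runs the group statistics,
#' and writes the results bundle to `out_dir`: `cells.tsv`,
#' `uptake_profile.tsv`, `recovery_matrix.csv`, `contrast.tsv`,
#' `stats.tsv` and `manifest.json` (configuration, seed and MD5 content
#' hash of every output, so identical config + seed gives identical
#' manifests).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); NULL computes
#'   the bundle without writing files.
#' @param verbose print per-stage progress lines.
#' @return Invisibly, a list with `cells`, `profiles`, `contrast`,
#'   `stats`, `recovery`, `anova` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "phiflux_config"))
  say <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  say("simulate")
  cohort <- stage("simulate", make_cohort(
    cohort_spec(config$scenario, config$n_risk, config$n_protective,
                config$jitter_cv, config$noise_cv, config$seed),
    condition = config$condition))
  say("analyze")
  res <- analyze_cohort(
    cohort$traces,
    genotype = cohort$truth$genotype,
    condition = config$condition,
    window_s = config$window_s, bin_width = config$bin_width,
    grid = list(start_s = config$grid_start_s,
                end_s = config$grid_end_s, step_s = config$grid_step_s))
  say("compare")
  stats_rows <- stage("compare", {
    plat_r <- res$cells$plateau_ph[res$cells$genotype == "risk"]
    plat_p <- res$cells$plateau_ph[res$cells$genotype == "protective"]
    if (length(plat_r) < 2 || length(plat_p) < 2)
      stop("insufficient data: need >= 2 cells per genotype",
           call. = FALSE)
    mw <- mann_whitney(plat_r, plat_p)
    an <- rm_two_way_anova(res$recovery, res$cells$genotype)
    sl <- compare_slopes(
      res$estimates[res$estimates$genotype == "risk", ],
      res$estimates[res$estimates$genotype == "protective", ])
    rows <- rbind(
      data.frame(test = "mann_whitney", effect = "plateau genotype",
                 statistic = mw$U, df = NA_real_, p = mw$p),
      data.frame(test = "rm_two_way_anova",
                 effect = paste0("recovery ", an$effect),
                 statistic = an$F, df = an$df1, p = an$p),
      data.frame(test = "slope_comparison", effect = "uptake slope",
                 statistic = sl$difference$slope$t,
                 df = sl$difference$df, p = sl$difference$slope$p))
    rows$p_adj <- bonferroni(rows$p, m = nrow(rows))
    list(rows = rows, anova = an, slopes = sl)
  })
  contrast <- stage("compare", cohort_contrast(res$cells))
  manifest <- list(package = "phiflux",
                   version = as.character(utils::packageVersion("phiflux")),
                   config = unclass(config), seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) {
      utils::write.table(d, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      f
    }
    files <- c(
      wt(res$cells, "cells.tsv"),
      wt(res$profiles, "uptake_profile.tsv"),
      wt(contrast, "contrast.tsv"),
      wt(stats_rows$rows, "stats.tsv"))
    rm_csv <- file.path(out_dir, "recovery_matrix.csv")
    utils::write.csv(data.frame(cell_id = rownames(res$recovery),
                                res$recovery, check.names = FALSE),
                     rm_csv, row.names = FALSE, quote = FALSE)
    files <- c(files, "recovery_matrix.csv")
    manifest$hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(manifest$hashes) <- files
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("done")
  invisible(list(cells = res$cells, profiles = res$profiles,
                 contrast = contrast, stats = stats_rows$rows,
                 recovery = res$recovery, anova = stats_rows$anova,
                 manifest = manifest))
}
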