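#' Canned simulation studies validating the reconstruction pipeline
#'
#' Runs one of the named validation studies on synthetic ground truth,
#' bootstrapping over pair-design resamples:
#' \describe{
#'   \item{loss_equivalence}{fits minimizing BCE and SE, with and without
#'     regularization, at N_b = 10; reports final BCE, SE and MAE per
#'     objective so their agreement can be checked.}
#'   \item{blocks_sweep}{MAE versus number of blocks N_b in
#'     \{1, 2, 4, ..., 128\}, with lambda in \{0, 10\}; reports the mean
#'     MAE ratio (no regularization over regularization).}
#'   \item{uncertainty_sweep}{MAE versus ground-truth uncertainty level at
#'     fixed N_b = 10, lambda in \{0, 10\}; reports per-level ratios.}
#'   \item{unknown_K}{ground truth with K = 5, fits at K = 3..7 with
#'     regularization; reports non-empty channel counts.}
#'   \item{resolution_sweep}{MAE versus grid resolution N.}
#' }
#'
#' Study problem sizes are desk-scale (N = 10-12 grids, 50 resamples by
#' default); \code{full_scale = TRUE} raises the resamples to 1000.
#'
#' @param study study name.
#' @param n_resamples pair-design resamples per condition.
#' @param seed master seed; every random draw in the study derives from it.
#' @param out_dir optional directory; when given, result tables are
#'   written there as CSV.
#' @param full_scale use 1000 resamples.
#' @return an object of class \code{study_result}: \code{study},
#'   \code{conditions} (per-condition summary with mean MAE and 95
#'   percent percentile interval), \code{per_resample}, plus
#'   study-specific entries (e.g. \code{mae_ratio}).
#' @export
run_study <- function(study = c("loss_equivalence", "blocks_sweep",
                                "uncertainty_sweep", "unknown_K",
                                "resolution_sweep"),
                      n_resamples = 50L, seed = 1L, out_dir = NULL,
                      full_scale = FALSE) {
  study <- match.arg(study)
  if (full_scale) n_resamples <- 1000L
  res <- switch(study,
    loss_equivalence = study_loss_equivalence(n_resamples, seed),
    blocks_sweep = study_blocks_sweep(n_resamples, seed),
    uncertainty_sweep = study_uncertainty_sweep(n_resamples, seed),
    unknown_K = study_unknown_k(n_resamples, seed),
    resolution_sweep = study_resolution_sweep(n_resamples, seed))
  res$study <- study
  res$seed <- seed
  res$n_resamples <- n_resamples
  class(res) <- "study_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$conditions,
                     file.path(out_dir, paste0(study, "_conditions.csv")),
                     row.names = FALSE)
    utils::write.csv(res$per_resample,
                     file.path(out_dir, paste0(study, "_resamples.csv")),
                     row.names = FALSE)
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s (%d resamples, seed %d)\n",
              x$study, x$n_resamples, x$seed))
  print(x$conditions, digits = 4)
  if (!is.null(x$mae_ratio))
    cat(sprintf("mean MAE ratio (lambda 0 / lambda 10): %.3f\n", x$mae_ratio))
  invisible(x)
}

# -- shared study conditions ------------------------------------------------
# Moderate-uncertainty K = 3 truth on an N = 10 grid; solver settings are
# the desk-scale choices documented in the methods vignette.
study_grid_N <- 10L
study_level_moderate <- 0.4
study_scale <- 1.5

study_truth <- function(N = study_grid_N, K = 3L,
                        level = study_level_moderate, seed = 1L) {
  sample_probmaps(grid_spec(N), K,
                  uncertainty_profile(level = level,
                                      spatial_scale = study_scale),
                  seed = seed)
}

study_solver <- function(loss = "se", seed = 1L) {
  solver_config(learning_rate = 15, stop_eps = 3e-10, max_iter = 3000L,
                loss = loss, seed = seed)
}

ci_summary <- function(df, value, by) {
  agg <- stats::aggregate(df[[value]], by = df[by],
                          FUN = function(x) c(mean = mean(x),
                                              lo = unname(stats::quantile(x, 0.025)),
                                              hi = unname(stats::quantile(x, 0.975))))
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out) <- c(by, paste0(value, c("_mean", "_lo", "_hi")))
  out
}

# keep only the first n blocks of a dataset (paired comparisons across N_b)
subset_blocks <- function(dataset, n) {
  response_dataset(dataset$data[dataset$data$block <= n, , drop = FALSE],
                   dataset$grid)
}

# -- individual studies -----------------------------------------------------

study_loss_equivalence <- function(n_resamples, seed) {
  K <- 3L; n_blocks <- 10L
  truth <- study_truth(seed = seed)
  grid <- truth$grid
  rows <- list()
  for (r in seq_len(n_resamples)) {
    s <- seed + 13L * r
    ps <- schedule_pairs(grid, K, seed = s)
    ds <- simulate_responses(truth, ps, n_blocks, seed = s)
    props <- empirical_proportions(ds)
    for (lambda in c(0, 10)) {
      reg <- reg_config(lambda = lambda)
      for (loss in c("se", "bce")) {
        # run both objectives to tight convergence so residual optimizer
        # error does not masquerade as loss-function disagreement
        fit <- fit_nonparametric(ds, K, reg = reg,
                                 solver = solver_config(stop_eps = 1e-9,
                                                        max_iter = 15000L,
                                                        loss = loss,
                                                        seed = s))
        rows[[length(rows) + 1L]] <- data.frame(
          resample = r, lambda = lambda, objective = loss,
          bce = bce_loss(fit$maps, ds),
          se = se_loss(fit$maps, props),
          mae = mean_absolute_error(fit$maps, truth))
      }
    }
  }
  per <- do.call(rbind, rows)
  cond <- Reduce(function(a, b) merge(a, b, by = c("lambda", "objective")),
                 lapply(c("bce", "se", "mae"),
                        function(v) ci_summary(per, v, c("lambda", "objective"))))
  list(conditions = cond, per_resample = per, truth = truth)
}

study_blocks_sweep <- function(n_resamples, seed,
                               blocks = c(1L, 2L, 4L, 8L, 16L, 32L, 64L,
                                          128L)) {
  K <- 3L
  truth <- study_truth(seed = seed)
  grid <- truth$grid
  rows <- list()
  for (r in seq_len(n_resamples)) {
    s <- seed + 13L * r
    ps <- schedule_pairs(grid, K, seed = s)
    full <- simulate_responses(truth, ps, max(blocks), seed = s)
    for (nb in blocks) {
      ds <- subset_blocks(full, nb)
      for (lambda in c(0, 10)) {
        fit <- fit_nonparametric(ds, K, reg = reg_config(lambda = lambda),
                                 solver = study_solver(seed = s))
        rows[[length(rows) + 1L]] <- data.frame(
          resample = r, n_blocks = nb, lambda = lambda,
          mae = mean_absolute_error(fit$maps, truth))
      }
    }
  }
  per <- do.call(rbind, rows)
  cond <- ci_summary(per, "mae", c("n_blocks", "lambda"))
  mm <- stats::reshape(cond[c("n_blocks", "lambda", "mae_mean")],
                       idvar = "n_blocks", timevar = "lambda",
                       direction = "wide")
  ratios <- mm$mae_mean.0 / mm$mae_mean.10
  list(conditions = cond, per_resample = per, truth = truth,
       ratio_by_blocks = data.frame(n_blocks = mm$n_blocks, ratio = ratios),
       mae_ratio = mean(ratios))
}

study_uncertainty_sweep <- function(n_resamples, seed,
                                    levels = c(0, 0.25, 0.5, 0.75, 1)) {
  K <- 3L; n_blocks <- 10L
  grid <- grid_spec(study_grid_N)
  truths <- lapply(levels, function(lv)
    sample_probmaps(grid, K,
                    uncertainty_profile(level = lv,
                                        spatial_scale = study_scale),
                    seed = seed))
  rows <- list()
  for (r in seq_len(n_resamples)) {
    s <- seed + 13L * r
    ps <- schedule_pairs(grid, K, seed = s)
    for (li in seq_along(levels)) {
      ds <- simulate_responses(truths[[li]], ps, n_blocks, seed = s + li)
      for (lambda in c(0, 10)) {
        fit <- fit_nonparametric(ds, K, reg = reg_config(lambda = lambda),
                                 solver = study_solver(seed = s))
        rows[[length(rows) + 1L]] <- data.frame(
          resample = r, level = levels[li], lambda = lambda,
          mae = mean_absolute_error(fit$maps, truths[[li]]))
      }
    }
  }
  per <- do.call(rbind, rows)
  cond <- ci_summary(per, "mae", c("level", "lambda"))
  mm <- stats::reshape(cond[c("level", "lambda", "mae_mean")],
                       idvar = "level", timevar = "lambda",
                       direction = "wide")
  keep <- mm$level > 0  # methods coincide on the deterministic case
  ratios <- mm$mae_mean.0[keep] / mm$mae_mean.10[keep]
  list(conditions = cond, per_resample = per,
       ratio_by_level = data.frame(level = mm$level[keep], ratio = ratios),
       mae_ratio = min(ratios))
}

study_unknown_k <- function(n_resamples, seed, fit_K = 3:7) {
  true_K <- 5L; n_blocks <- 10L; N <- 12L
  truth <- sample_probmaps(grid_spec(N), true_K,
                           uncertainty_profile(level = study_level_moderate,
                                               spatial_scale = study_scale),
                           seed = seed)
  grid <- truth$grid
  rows <- list()
  for (r in seq_len(n_resamples)) {
    s <- seed + 13L * r
    ps <- schedule_pairs(grid, true_K, seed = s)
    ds <- simulate_responses(truth, ps, n_blocks, seed = s)
    for (Kf in fit_K) {
      # channel suppression requires near-convergence, hence the tighter
      # stopping rule than in the sweep studies
      fit <- fit_nonparametric(ds, Kf, reg = reg_config(lambda = 10),
                               solver = solver_config(stop_eps = 1e-11,
                                                      max_iter = 10000L,
                                                      seed = s))
      rows[[length(rows) + 1L]] <- data.frame(
        resample = r, fit_K = Kf,
        n_nonempty = count_nonempty_segments(fit$maps))
    }
  }
  per <- do.call(rbind, rows)
  cond <- stats::aggregate(n_nonempty ~ fit_K, data = per,
                           FUN = function(x) c(median = stats::median(x),
                                               mean = mean(x)))
  cond <- cbind(fit_K = cond$fit_K, as.data.frame(cond$n_nonempty))
  list(conditions = cond, per_resample = per, truth = truth,
       true_K = true_K)
}

study_resolution_sweep <- function(n_resamples, seed,
                                   resolutions = c(6L, 9L, 12L, 15L)) {
  K <- 3L; n_blocks <- 10L
  rows <- list()
  for (N in resolutions) {
    truth <- study_truth(N = N, seed = seed)
    grid <- truth$grid
    for (r in seq_len(n_resamples)) {
      s <- seed + 13L * r
      ps <- schedule_pairs(grid, K, seed = s)
      ds <- simulate_responses(truth, ps, n_blocks, seed = s)
      for (lambda in c(0, 10)) {
        fit <- fit_nonparametric(ds, K, reg = reg_config(lambda = lambda),
                                 solver = study_solver(seed = s))
        rows[[length(rows) + 1L]] <- data.frame(
          resample = r, N = N, lambda = lambda,
          mae = mean_absolute_error(fit$maps, truth))
      }
    }
  }
  per <- do.call(rbind, rows)
  list(conditions = ci_summary(per, "mae", c("N", "lambda")),
       per_resample = per)
}

#' Plot a sweep-type study result
#'
#' Mean MAE with 95 percent percentile band against the swept condition,
#' one curve per regularization setting.
#'
#' @param x a \code{study_result} from [run_study()] (blocks, uncertainty
#'   or resolution sweep).
#' @param ... passed to [graphics::plot()].
#' @export
plot.study_result <- function(x, ...) {
  cond <- x$conditions
  xvar <- intersect(c("n_blocks", "level", "N"), names(cond))[1L]
  if (is.na(xvar) || !"lambda" %in% names(cond))
    stop("plotting is defined for the sweep studies", call. = FALSE)
  xs <- sort(unique(cond[[xvar]]))
  logx <- identical(xvar, "n_blocks")
  graphics::plot(range(xs), range(c(cond$mae_lo, cond$mae_hi)), type = "n",
                 xlab = xvar, ylab = "MAE to ground truth",
                 log = if (logx) "x" else "", ...)
  cols <- c(`0` = "grey30", `10` = "grey65")
  for (lam in unique(cond$lambda)) {
    cc <- cond[cond$lambda == lam, ]
    cc <- cc[order(cc[[xvar]]), ]
    graphics::polygon(c(cc[[xvar]], rev(cc[[xvar]])),
                      c(cc$mae_lo, rev(cc$mae_hi)),
                      col = grDevices::adjustcolor(cols[[as.character(lam)]], 0.3),
                      border = NA)
    graphics::lines(cc[[xvar]], cc$mae_mean, col = cols[[as.character(lam)]],
                    lwd = 2)
  }
  graphics::legend("topright", legend = paste("lambda =", unique(cond$lambda)),
                   col = cols[as.character(unique(cond$lambda))], lwd = 2,
                   bty = "n")
  invisible(x)
}

#' One-shot analysis pipeline: read, validate, fit, write
#'
#' Reads a response CSV, validates coverage, fits either the
#' non-parametric or the parametric model according to the configuration,
#' and (optionally) writes the probabilistic maps, segmentation map,
#' entropy map, loss trace and a JSON manifest recording all settings.
#'
#' @param responses_path CSV of responses (see [read_responses()]).
#' @param config list with entries \code{N} (grid side, required),
#'   \code{K} (required), \code{model} ("nonparam", default, or
#'   "logistic"), \code{lambda}, \code{kernel}, \code{loss},
#'   \code{learning_rate}, \code{stop_eps}, \code{max_iter}, \code{seed},
#'   \code{features_path} (required for the logistic model),
#'   \code{parametrization}, \code{out_dir} (optional output directory).
#' @return list with \code{fit}, \code{entropy}, \code{manifest} and the
#'   vector of \code{files} written.
#' @export
run_pipeline <- function(responses_path, config) {
  defaults <- list(model = "nonparam", lambda = 10, kernel = "laplacian4",
                   loss = "se", learning_rate = 0.05, stop_eps = 1e-8,
                   max_iter = 10000L, seed = 1L, parametrization = "free",
                   features_path = NULL, out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  for (f in c("N", "K"))
    if (is.null(config[[f]]))
      stop(sprintf("config must provide '%s'", f), call. = FALSE)
  grid <- grid_spec(config$N)
  dataset <- read_responses(responses_path, grid)
  rep <- validate_pairset(pair_set(dataset$data$i, dataset$data$j, grid))
  if (!rep$coverage)
    warning(sprintf("responses do not cover %d grid element(s): %s",
                    length(rep$uncovered),
                    paste(utils::head(rep$uncovered, 10L), collapse = ", ")),
            call. = FALSE)
  reg <- reg_config(lambda = config$lambda, kernel = config$kernel)
  if (config$model == "logistic") {
    if (is.null(config$features_path))
      stop("the logistic model requires config$features_path", call. = FALSE)
    fm <- read_features(config$features_path, grid)
    fit <- fit_parametric(dataset, fm, config$K, reg = reg,
                          parametrization = config$parametrization,
                          seed = config$seed)
  } else {
    solver <- solver_config(learning_rate = config$learning_rate,
                            stop_eps = config$stop_eps,
                            max_iter = config$max_iter,
                            loss = config$loss, seed = config$seed)
    fit <- fit_nonparametric(dataset, config$K, reg = reg, solver = solver)
  }
  ent <- entropy_map(fit$maps)
  manifest <- list(
    responses = responses_path,
    config = config[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    n_trials = nrow(dataset$data), n_blocks = dataset$n_blocks,
    coverage = rep$coverage,
    package_version = as.character(utils::packageVersion("probseg")))
  files <- character(0)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    files <- c(files, write_probmaps(fit$maps, file.path(od, "maps")))
    files <- c(files, write_segmap(to_segmentation(fit$maps),
                                   file.path(od, "segmentation.csv")))
    efile <- file.path(od, "entropy.csv")
    utils::write.table(ent$map$value, efile, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, efile)
    if (!is.null(fit$loss_trace)) {
      tfile <- file.path(od, "loss_trace.csv")
      utils::write.csv(data.frame(iteration = seq_along(fit$loss_trace) - 1L,
                                  loss = fit$loss_trace),
                       tfile, row.names = FALSE)
      files <- c(files, tfile)
    }
    mfile <- file.path(od, "manifest.json")
    jsonlite::write_json(manifest, mfile, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, mfile)
  }
  list(fit = fit, entropy = ent, manifest = manifest, files = files)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a feature map to CSV
#' @param features a [feature_map()].
#' @param path output file (columns row, col, f1..fD; 1-based coordinates).
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_map"))
  cc <- cell_coords(features$grid, seq_len(n_cells(features$grid)))
  out <- cbind(cc, as.data.frame(features$values))
  names(out) <- c("row", "col", paste0("f", seq_len(features$D)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature map from CSV
#' @param path file written by [write_features()].
#' @param grid a [grid_spec()].
#' @export
read_features <- function(path, grid) {
  raw <- utils::read.csv(path, header = TRUE)
  idx <- cell_index(grid, raw$row, raw$col)
  v <- as.matrix(raw[setdiff(names(raw), c("row", "col"))])
  feature_map(v[order(idx), , drop = FALSE], grid)
}
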