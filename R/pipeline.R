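#' Pipeline run configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline. Defaults are
#' the published acquisition and model settings: 1926 Hz sampling, order-10
#' Butterworth 20 Hz high-pass / 400 Hz low-pass, 0.05 correlation-threshold
#' step, 100 trees and 10 random-forest seeds.
#'
#' @param fs sampling rate (Hz).
#' @param hp_order,hp_cutoff high-pass order and cutoff (Hz).
#' @param lp_order,lp_cutoff low-pass order and cutoff (Hz).
#' @param env_cutoff envelope smoothing cutoff (Hz).
#' @param prominence_fraction burst-detection derivative threshold fraction.
#' @param min_interval minimum same-type event spacing (s).
#' @param spectrum_power "magnitude" or "squared" spectrum convention.
#' @param cps_refine breakpoint-grid refinement factor.
#' @param threshold_step selection sweep step in (0, 1].
#' @param n_trees,n_seeds forest size and final seed count.
#' @param sweep_seeds seed count when scoring sweep candidates.
#' @param window,hop stride window/hop for time-feature rows.
#' @param feature_set "frequency", "time_domain" or "time_event".
#' @param channel channel for the frequency model.
#' @param mode "classify" (phase classes) or "regress" (lactate).
#' @param seed master RNG seed.
#' @return a `run_config` list.
#' @export
run_config <- function(fs = 1926,
                       hp_order = 10, hp_cutoff = 20,
                       lp_order = 10, lp_cutoff = 400,
                       env_cutoff = 5, prominence_fraction = 0.2,
                       min_interval = 0.4,
                       spectrum_power = c("magnitude", "squared"),
                       cps_refine = 1,
                       threshold_step = 0.05,
                       n_trees = 100, n_seeds = 10, sweep_seeds = 3,
                       window = 20, hop = 5,
                       feature_set = c("frequency", "time_domain",
                                       "time_event"),
                       channel = "RVL",
                       mode = c("classify", "regress"),
                       seed = 1) {
  spectrum_power <- match.arg(spectrum_power)
  feature_set <- match.arg(feature_set)
  mode <- match.arg(mode)
  if (threshold_step <= 0 || threshold_step > 1)
    stop_with("config_error", "threshold_step must be in (0, 1]")
  if (n_trees < 1) stop_with("config_error", "n_trees must be >= 1")
  if (!(hp_cutoff < lp_cutoff && lp_cutoff < fs / 2))
    stop_with("config_error", "need hp_cutoff < lp_cutoff < Nyquist")
  structure(as.list(environment()), class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_with("pipeline_error", "[stage %s] %s", name, conditionMessage(e))
  })
}

#' @noRd
log_stage <- function(name, ...) {
  message(sprintf("[%s] %s", name, sprintf(...)))
}

#' Run the full fatigue-classification pipeline on one session
#'
#' preprocess -> burst detection -> feature extraction -> lactate change-point
#' labels -> correlation-threshold selection sweep -> random forest ->
#' report. In "classify" mode rows are labeled with the fatigue phase
#' (aerobic / anaerobic / recovery) of their timestamp under the fitted
#' change-point model and scored by per-class out-of-bag ROC AUC; in
#' "regress" mode the target is the Catmull-Rom-interpolated lactate value
#' and the score is the out-of-bag R-squared.
#'
#' @param semg a [recording()] or path to a recording CSV.
#' @param lactate a [lactate_series()] or path to a lactate CSV.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, the feature matrix,
#'   labels and JSON report are written there.
#' @return a `model_report` list: mode, counts per stage, change-point fit,
#'   selection table, selected features, per-class AUC (or R2), and
#'   Kruskal-Wallis results for the selected features.
#' @export
run_pipeline <- function(semg, lactate, config = run_config(),
                         out_dir = NULL) {
  rec <- stage("read", {
    if (inherits(semg, "semg_recording")) semg
    else read_recording(semg, fs = config$fs)
  })
  lac <- stage("read", {
    if (inherits(lactate, "lactate_series")) lactate else read_lactate(lactate)
  })
  pre <- stage("preprocess", bandlimit(
    rec,
    lp = filter_spec("lowpass", config$lp_order, config$lp_cutoff, 450, 60),
    hp = filter_spec("highpass", config$hp_order, config$hp_cutoff, 10, 60)))
  bursts <- stage("burst_detect", detect_bursts_all(
    pre, config$env_cutoff, config$prominence_fraction, config$min_interval))
  log_stage("burst_detect", "bursts per channel: %s",
            paste(sprintf("%s=%d", names(bursts),
                          vapply(bursts, nrow, 0L)), collapse = " "))
  feats <- stage("features", {
    if (config$feature_set == "frequency") {
      ch <- config$channel
      if (!ch %in% rec$channel_ids)
        stop_with("config_error", "channel %s not in recording", ch)
      fm <- channel_freq_features(pre$samples[, ch], pre$fs, bursts[[ch]],
                                  config$spectrum_power)
      names(fm)[1] <- "t_s"
      fm
    } else {
      cycles <- build_stride_cycles(bursts)
      log_stage("features", "%d stride cycles (%d complete)",
                nrow(cycles), sum(cycles$complete))
      rows <- stride_feature_rows(cycles, pre)
      wf <- windowed_time_features(rows, config$window, config$hop)
      if (config$feature_set == "time_event")
        wf <- wf[, c("t_s", time_feature_names()[time_event_indices()])]
      wf
    }
  })
  if (!nrow(feats)) stop_with("pipeline_error", "[stage features] no rows")
  cps <- stage("cps", fit_change_points(lac, refine = config$cps_refine))
  in_range <- feats$t_s >= lac$times[1] & feats$t_s <= lac$t_max
  if (any(!in_range))
    log_stage("cps", "dropped %d row(s) outside the lactate time range",
              sum(!in_range))
  feats <- feats[in_range, , drop = FALSE]
  X <- normalize01(feats[, setdiff(names(feats), "t_s"), drop = FALSE])
  target <- stage("labels", {
    if (config$mode == "classify") {
      cls <- assign_classes(cps, feats$t_s)
      if (length(unique(cls)) < 2L)
        stop_with("pipeline_error", "fewer than 2 phase classes in session")
      factor(cls, levels = sort(unique(cls)))
    } else {
      y <- interpolate_lactate(lac, feats$t_s)
      rng <- range(y)
      (y - rng[1]) / max(diff(rng), .Machine$double.eps)
    }
  })
  log_stage("features", "%d rows x %d features", nrow(X), ncol(X))
  sweep <- stage("model", threshold_sweep_select(
    X, target, mode = config$mode, step = config$threshold_step,
    n_trees = config$n_trees, n_seeds = config$n_seeds,
    sweep_seeds = config$sweep_seeds, master_seed = config$seed))
  log_stage("model", "best tau %.2f, %d feature(s) selected",
            sweep$best_tau, length(sweep$selected))
  kw <- NULL
  if (config$mode == "classify") {
    kw <- lapply(sweep$selected, function(nm) {
      r <- kruskal_wallis(X[[nm]], target)
      list(feature = nm, H = r$H, p = r$p,
           mean_ranks = as.list(r$mean_ranks))
    })
  }
  report <- list(
    mode = config$mode,
    n_trees = config$n_trees, n_seeds = config$n_seeds, seed = config$seed,
    feature_set = config$feature_set,
    channel = if (config$feature_set == "frequency") config$channel else NULL,
    n_rows = nrow(X), n_features = ncol(X),
    cps = list(t_prime_s = cps$t_prime, t_dprime_s = cps$t_dprime,
               slopes_mmol_per_l_per_s = c(cps$a1, cps$a2, cps$a3),
               intercepts_mmol_per_l = c(cps$b1, cps$b2, cps$b3),
               sse = cps$sse),
    best_tau = sweep$best_tau,
    selected_features = sweep$selected,
    sweep = sweep$table,
    auc = if (config$mode == "classify")
      list(per_class = as.list(sweep$auc$auc),
           macro_avg = sweep$auc$macro_avg) else NULL,
    oob_r2 = if (config$mode == "regress") sweep$model$r2 else NULL,
    kruskal_wallis = kw)
  class(report) <- "model_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(t_s = feats$t_s, X),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(data.frame(t_s = feats$t_s, target = target),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a model report to JSON
#'
#' With a fixed config and seed the pipeline is deterministic, so two runs
#' produce byte-identical report files.
#'
#' @param report a `model_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s / %s, %d rows x %d features\n",
              x$mode, x$feature_set, x$n_rows, x$n_features))
  cat(sprintf("  CPS: t' = %.0f s, t'' = %.0f s\n",
              x$cps$t_prime_s, x$cps$t_dprime_s))
  cat(sprintf("  best tau = %.2f (%d selected)\n",
              x$best_tau, length(x$selected_features)))
  if (!is.null(x$auc))
    cat(sprintf("  OOB AUC per class: %s (macro %.3f)\n",
                paste(sprintf("%s=%.3f", names(x$auc$per_class),
                              unlist(x$auc$per_class)), collapse = " "),
                x$auc$macro_avg))
  if (!is.null(x$oob_r2)) cat(sprintf("  OOB R2 = %.3f\n", x$oob_r2))
  invisible(x)
}

#' Run the pipeline over a pooled synthetic cohort
#'
#' Generates `n_participants` jittered sessions one at a time, extracts the
#' frequency features of `channel`, labels rows with the phase classes of
#' each participant's own fitted change-point model, normalizes per session,
#' pools everything, and runs the selection sweep plus final forest on the
#' pooled matrix.
#'
#' @param n_participants cohort size (default 12).
#' @param base_spec cohort-level [session_spec()].
#' @param config a [run_config()].
#' @param channel channel for the frequency model (default from config).
#' @return list: `features` (pooled normalized matrix), `labels`,
#'   `participant` ids, `sweep` (from [threshold_sweep_select()]), `auc`,
#'   `kw_best_band` (Kruskal-Wallis on the selected band-power feature with
#'   the largest |rs|).
#' @export
run_cohort <- function(n_participants = 12, base_spec = session_spec(),
                       config = run_config(), channel = config$channel) {
  specs <- participant_specs(n_participants, config$seed, base_spec)
  pooled <- list(); labels <- list(); pid <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    lac <- gen_lactate_profile(sp)
    cps <- fit_change_points(lac$series)
    ses <- gen_semg_session(sp)
    pre <- bandlimit(ses$recording)
    b <- detect_bursts(pre$samples[, channel], pre$fs, config$env_cutoff,
                       config$prominence_fraction, config$min_interval)
    fm <- channel_freq_features(pre$samples[, channel], pre$fs, b,
                                config$spectrum_power)
    ok <- fm$t_mid_s <= lac$series$t_max
    fm <- fm[ok, , drop = FALSE]
    X <- normalize01(fm[, freq_feature_names(), drop = FALSE])
    pooled[[i]] <- X
    labels[[i]] <- assign_classes(cps, fm$t_mid_s)
    pid[[i]] <- rep(i, nrow(X))
    log_stage("cohort", "participant %d: %d rows", i, nrow(X))
    rm(ses, pre); gc(verbose = FALSE)
  }
  X <- do.call(rbind, pooled)
  y <- factor(unlist(labels), levels = 1:3)
  sweep <- threshold_sweep_select(
    X, y, mode = "classify", step = config$threshold_step,
    n_trees = config$n_trees, n_seeds = config$n_seeds,
    sweep_seeds = config$sweep_seeds, master_seed = config$seed)
  band_sel <- grep("^p_band_", sweep$selected, value = TRUE)
  kw_best <- NULL
  if (length(band_sel)) {
    rs_band <- sweep$rs[sweep$rs$feature %in% band_sel, ]
    best_band <- rs_band$feature[which.max(abs(rs_band$rs))]
    r <- kruskal_wallis(X[[best_band]], y)
    kw_best <- list(feature = best_band, H = r$H, p = r$p,
                    mean_ranks = r$mean_ranks)
  }
  list(features = X, labels = y, participant = unlist(pid),
       sweep = sweep, auc = sweep$auc, kw_best_band = kw_best)
}
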