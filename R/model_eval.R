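#' Spearman rank correlation
#'
#' Computed as the product-moment correlation of mid-ranks, which reduces to
#' the classical `1 - 6*sum(d^2) / (n*(n^2-1))` when there are no ties. A
#' two-sided p-value is obtained from the t approximation
#' `t = r*sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rs`, `p`, and `undefined` (TRUE when either vector is
#'   constant, in which case `rs = 0` for selection purposes).
#' @export
spearman_rs <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    stop_with("config_error", "x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rs = 0, p = 1, undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  rs <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  rs <- max(-1, min(1, rs))
  p <- if (abs(rs) >= 1) 0 else {
    tt <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rs = rs, p = p, undefined = FALSE)
}

#' Normalize feature columns to [0, 1]
#'
#' Min-max normalization over the session, the scaling applied to both
#' features and the interpolated lactate target before correlation and model
#' training. Constant columns are set to 0 and flagged.
#'
#' @param df data.frame of numeric columns.
#' @return data.frame with attribute `constant_cols`.
#' @export
normalize01 <- function(df) {
  const <- character(0)
  out <- df
  for (nm in names(df)) {
    rng <- range(df[[nm]])
    if (diff(rng) == 0) {
      out[[nm]] <- rep(0, nrow(df)); const <- c(const, nm)
    } else {
      out[[nm]] <- (df[[nm]] - rng[1]) / diff(rng)
    }
  }
  attr(out, "constant_cols") <- const
  out
}

#' Out-of-bag coefficient of determination
#'
#' `R^2 = 1 - sum((Y - Yhat)^2) / sum((Y - mean(Y))^2)`; 1 is perfect
#' regression, 0 the naive mean predictor.
#'
#' @param y actual values.
#' @param y_hat out-of-bag predictions.
#' @return R-squared (<= 1; can be negative for worse-than-naive models).
#' @export
oob_r2 <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop_with("config_error", "y and y_hat must have equal length")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0)
    stop_with("undefined_r2", "target has zero variance")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Train a random forest with multi-seed out-of-bag evaluation
#'
#' Fits `n_seeds` independent 100-tree forests (seeds derived
#' deterministically from `master_seed`) and pools their out-of-bag
#' predictions: class-vote fractions are averaged across seeds
#' (classification) and the per-seed out-of-bag R-squared values are averaged
#' (regression).
#'
#' @param X data.frame of features.
#' @param y factor (classification) or numeric (regression) target.
#' @param n_trees trees per forest (default 100).
#' @param n_seeds number of independent seedings (default 10).
#' @param mode "classify" or "regress".
#' @param master_seed integer master seed.
#' @return list: `mode`, `votes` (rows x classes, classification),
#'   `oob_pred` (averaged OOB predictions), `oob_accuracy` (classification),
#'   `r2` (mean over seeds) and `r2_by_seed` (regression).
#' @export
train_rf <- function(X, y, n_trees = 100, n_seeds = 10,
                     mode = c("classify", "regress"), master_seed = 1) {
  mode <- match.arg(mode)
  if (!nrow(X) || !ncol(X))
    stop_with("config_error", "empty feature matrix")
  d <- X
  if (mode == "classify") {
    y <- factor(y)
    if (nlevels(y) < 2L)
      stop_with("config_error", "classification needs >= 2 classes")
    d$.target <- y
    acc <- 0
    votes <- NULL
    for (s in seq_len(n_seeds)) {
      rf <- ranger::ranger(
        dependent.variable.name = ".target", data = d,
        num.trees = n_trees, probability = TRUE,
        num.threads = 1, seed = derive_seed(master_seed, s))
      v <- rf$predictions
      if (anyNA(v)) {
        warning("rows never out-of-bag; their votes set to uniform")
        v[is.na(v)] <- 1 / nlevels(y)
      }
      votes <- if (is.null(votes)) v else votes + v
    }
    votes <- votes / n_seeds
    pred <- factor(levels(y)[max.col(votes, ties.method = "first")],
                   levels = levels(y))
    list(mode = mode, votes = votes, classes = levels(y),
         oob_accuracy = mean(pred == y))
  } else {
    y <- as.numeric(y)
    d$.target <- y
    preds <- NULL; r2s <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      rf <- ranger::ranger(
        dependent.variable.name = ".target", data = d,
        num.trees = n_trees,
        num.threads = 1, seed = derive_seed(master_seed, s))
      p <- rf$predictions
      if (anyNA(p)) {
        warning("rows never out-of-bag; predicted as target mean")
        p[is.na(p)] <- mean(y)
      }
      r2s[s] <- oob_r2(y, p)
      preds <- if (is.null(preds)) p else preds + p
    }
    list(mode = mode, oob_pred = preds / n_seeds,
         r2 = mean(r2s), r2_by_seed = r2s)
  }
}

#' One-vs-rest ROC AUC per class
#'
#' For each class, the out-of-bag vote fraction for that class scores a
#' one-vs-rest ROC curve; the area is computed by the rank (Mann-Whitney)
#' identity, which equals the trapezoidal area with ties counted one half.
#'
#' @param votes matrix of vote fractions (rows x classes, column names =
#'   class labels).
#' @param labels true class labels.
#' @return list with `auc` (named per class, NA for classes absent from
#'   `labels`) and `macro_avg` over the defined classes.
#' @export
roc_auc_per_class <- function(votes, labels) {
  labels <- as.character(labels)
  cls <- colnames(votes)
  auc <- stats::setNames(rep(NA_real_, length(cls)), cls)
  for (k in cls) {
    pos <- labels == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warning(sprintf("class %s absent from labels; AUC undefined", k))
      next
    }
    r <- rank(votes[, k])
    auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(auc = auc, macro_avg = mean(auc, na.rm = TRUE))
}

#' Kruskal-Wallis test with per-class mean ranks
#'
#' Rank-based test that the grouped samples share a location, with the
#' tie-corrected H statistic and chi-square p-value from
#' [stats::kruskal.test()], augmented with the per-group mean ranks used to
#' read off which fatigue class sits highest.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups).
#' @return list with `H`, `p`, `mean_ranks` (named per group).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop_with("config_error", "need >= 2 groups")
  mr <- tapply(rank(values), groups, mean)
  mr <- stats::setNames(as.numeric(mr), names(mr))
  if (length(unique(values)) == 1L) {
    warning("all values identical; H = 0")
    return(list(H = 0, p = 1, mean_ranks = mr))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value, mean_ranks = mr)
}

#' Correlation-threshold feature-selection sweep
#'
#' Computes the Spearman correlation of every (normalized) feature with the
#' target, then sweeps a threshold tau from 0 to 1 in steps of
#' `step`: at each tau the features with `|rs| >= tau` are kept and a
#' random-forest model is trained and scored out-of-bag (macro-average AUC
#' for classification, R-squared for regression). The best tau is the one
#' with the highest score; ties go to the larger tau (fewer features).
#' Scores are cached per distinct feature set, and the sweep is scored with
#' `sweep_seeds` forests; the returned `best` model is refit with the full
#' `n_seeds`.
#'
#' @param features data.frame of normalized features.
#' @param target numeric target (regression) or class labels
#'   (classification; correlation uses the numeric class 1/2/3, which is
#'   ordinal in time).
#' @param mode "classify" or "regress".
#' @param step threshold increment (default 0.05).
#' @param n_trees,n_seeds forest size and seed count for the final model.
#' @param sweep_seeds seed count used when scoring candidate sets.
#' @param master_seed integer master seed.
#' @return list: `table` (data.frame tau / n_selected / score), `rs`
#'   (per-feature correlation and p), `best_tau`, `selected` (feature names
#'   at the best tau), `model` (the refit [train_rf()] result), `auc`
#'   ([roc_auc_per_class()] result, classification only).
#' @export
threshold_sweep_select <- function(features, target,
                                   mode = c("classify", "regress"),
                                   step = 0.05, n_trees = 100, n_seeds = 10,
                                   sweep_seeds = 3, master_seed = 1) {
  mode <- match.arg(mode)
  target_num <- as.numeric(target)
  rs_tab <- do.call(rbind, lapply(names(features), function(nm) {
    r <- spearman_rs(features[[nm]], target_num)
    data.frame(feature = nm, rs = r$rs, p = r$p, undefined = r$undefined)
  }))
  taus <- seq(0, 1, by = step)
  cache <- new.env(parent = emptyenv())
  score_set <- function(sel) {
    key <- paste(sel, collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- train_rf(features[sel], target, n_trees = n_trees,
                    n_seeds = sweep_seeds, mode = mode,
                    master_seed = master_seed)
    sc <- if (mode == "classify")
      roc_auc_per_class(fit$votes, target)$macro_avg else fit$r2
    cache[[key]] <- sc
    sc
  }
  rows <- list(); best_tau <- NA_real_; best_score <- -Inf
  for (tau in taus) {
    sel <- rs_tab$feature[abs(rs_tab$rs) >= tau]
    if (!length(sel)) {
      message(sprintf("tau = %.2f selects no features; skipped", tau))
      next
    }
    sc <- score_set(sel)
    rows[[length(rows) + 1L]] <-
      data.frame(tau = tau, n_selected = length(sel), score = sc)
    if (sc >= best_score) { best_score <- sc; best_tau <- tau }
  }
  if (!length(rows))
    stop_with("fitting_error", "no threshold selected any features")
  selected <- rs_tab$feature[abs(rs_tab$rs) >= best_tau]
  model <- train_rf(features[selected], target, n_trees = n_trees,
                    n_seeds = n_seeds, mode = mode, master_seed = master_seed)
  auc <- if (mode == "classify")
    roc_auc_per_class(model$votes, target) else NULL
  list(table = do.call(rbind, rows), rs = rs_tab,
       best_tau = best_tau, selected = selected, model = model, auc = auc)
}
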