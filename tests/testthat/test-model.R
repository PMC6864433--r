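test_that("Spearman coefficient reproduces the rank formula and hand cases", {
  expect_equal(spearman_rs(1:10, (1:10)^3)$rs, 1)       # monotone transform
  expect_equal(spearman_rs(1:10, 10:1)$rs, -1)
  expect_equal(spearman_rs(c(1, 2, 3), c(2, 1, 3))$rs, 0.5)  # 1 - 6*2/24
  r <- spearman_rs(rep(1, 5), 1:5)
  expect_true(r$undefined)
  expect_equal(r$rs, 0)
  # tie-free vectors: matches 1 - 6*sum(d^2)/(n(n^2-1)) exactly
  set.seed(51)
  for (rep in 1:1000) {
    n <- sample(5:30, 1)
    x <- sample(n); y <- sample(n)
    d <- rank(x) - rank(y)
    direct <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(spearman_rs(x, y)$rs, direct, tolerance = 1e-12)
  }
  # with ties: agrees with the base midrank implementation
  set.seed(52)
  x <- sample(1:5, 40, TRUE); y <- sample(1:5, 40, TRUE)
  expect_equal(spearman_rs(x, y)$rs,
               suppressWarnings(stats::cor(x, y, method = "spearman")),
               tolerance = 1e-12)
})

test_that("out-of-bag R2 hand cases", {
  y <- c(1, 2, 3)
  expect_equal(oob_r2(y, y), 1)
  expect_equal(oob_r2(y, rep(mean(y), 3)), 0)
  expect_equal(oob_r2(y, c(1, 2, 4)), 0.5)
  expect_error(oob_r2(rep(2, 4), rep(2, 4)), "zero variance")
})

test_that("Kruskal-Wallis hand case H = 7.2 and identical-group degeneracy", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                      rep(c("a", "b", "c"), each = 3))
  expect_equal(r$H, 7.2, tolerance = 1e-12)
  expect_equal(unname(r$mean_ranks), c(2, 5, 8))
  expect_warning(r0 <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3)),
                 "identical")
  expect_equal(r0$H, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("Kruskal-Wallis holds its nominal type-I error under the null", {
  set.seed(53)
  rej <- mean(replicate(1000, {
    kruskal_wallis(rnorm(30), rep(1:3, each = 10))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("AUC matches the pairwise oracle and is monotone-invariant", {
  # perfectly ordered scores
  votes <- cbind("1" = c(0.9, 0.8, 0.2, 0.1), "2" = c(0.1, 0.2, 0.8, 0.9))
  labels <- c(1, 1, 2, 2)
  r <- roc_auc_per_class(votes, labels)
  expect_equal(unname(r$auc["1"]), 1)
  expect_equal(unname(r$auc["2"]), 1)
  # small instance with ties against exhaustive pairwise comparison
  votes2 <- cbind("1" = c(0.5, 0.5, 0.3, 0.7), "2" = c(0.5, 0.5, 0.7, 0.3))
  labels2 <- c(1, 2, 2, 1)
  r2 <- roc_auc_per_class(votes2, labels2)
  expect_equal(unname(r2$auc["1"]),
               pairwise_auc(votes2[, "1"], labels2 == 1))
  expect_equal(unname(r2$auc["2"]),
               pairwise_auc(votes2[, "2"], labels2 == 2))
  # monotone transform of scores leaves AUC unchanged
  set.seed(54)
  sc <- runif(40); lab <- sample(1:2, 40, TRUE)
  v1 <- cbind("1" = sc, "2" = 1 - sc)
  v2 <- cbind("1" = exp(3 * sc), "2" = -exp(3 * sc))
  expect_equal(roc_auc_per_class(v1, lab)$auc,
               roc_auc_per_class(v2, lab)$auc)
  # label-independent scores sit near 0.5
  set.seed(55)
  big <- cbind("1" = runif(4000), "2" = runif(4000))
  labb <- sample(1:2, 4000, TRUE)
  expect_lt(abs(roc_auc_per_class(big, labb)$auc[["1"]] - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(56)
  sc <- runif(60); lab <- sample(1:2, 60, TRUE)
  votes <- cbind("1" = sc, "2" = 1 - sc)
  ours <- roc_auc_per_class(votes, lab)$auc[["1"]]
  ref <- as.numeric(pROC::auc(pROC::roc(lab == 1, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random forest separates separable classes and is deterministic", {
  set.seed(57)
  n <- 300
  X <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
                  f2 = c(rnorm(n / 2, 4), rnorm(n / 2, 0)))
  y <- factor(rep(1:2, each = n / 2))
  fit <- train_rf(X, y, n_trees = 100, n_seeds = 3, mode = "classify",
                  master_seed = 5)
  expect_gte(fit$oob_accuracy, 0.95)
  fit2 <- train_rf(X, y, n_trees = 100, n_seeds = 3, mode = "classify",
                   master_seed = 5)
  expect_identical(fit$votes, fit2$votes)
  # shuffled labels give chance-level AUC
  ys <- sample(y)
  fs <- train_rf(X, ys, n_trees = 100, n_seeds = 3, mode = "classify",
                 master_seed = 5)
  auc <- roc_auc_per_class(fs$votes, ys)
  expect_lt(abs(auc$auc[["1"]] - 0.5), 0.1)
  expect_error(train_rf(X, factor(rep(1, n)), mode = "classify"),
               ">= 2 classes")
})

test_that("regression forests recover signal and stay near zero on noise", {
  set.seed(58)
  n <- 300
  X <- data.frame(f1 = runif(n), f2 = runif(n), f3 = runif(n))
  y <- 3 * X$f1 + rnorm(n, 0, 0.1)
  fit <- train_rf(X, y, n_trees = 100, n_seeds = 3, mode = "regress",
                  master_seed = 6)
  expect_gt(fit$r2, 0.7)
  r2s <- vapply(1:10, function(s) {
    train_rf(X, rnorm(n), n_trees = 50, n_seeds = 1, mode = "regress",
             master_seed = s)$r2
  }, numeric(1))
  expect_lt(median(r2s), 0.1)  # pure-noise target: OOB R2 concentrates <= 0
})

test_that("threshold sweep nests selections and keeps perfect features to tau 1", {
  set.seed(59)
  n <- 150
  target <- runif(n)
  X <- data.frame(perfect = target,
                  good = target + rnorm(n, 0, 0.3),
                  noise1 = runif(n), noise2 = runif(n))
  sw <- threshold_sweep_select(X, target, mode = "regress", n_seeds = 2,
                               sweep_seeds = 1, master_seed = 7)
  expect_true("perfect" %in% sw$selected)
  expect_equal(abs(sw$rs$rs[sw$rs$feature == "perfect"]), 1)
  # tau = 0 row selects all features
  expect_equal(sw$table$n_selected[sw$table$tau == 0], ncol(X))
  # nesting: n_selected non-increasing in tau
  expect_true(all(diff(sw$table$n_selected) <= 0))
})

test_that("sweep retains informative features among noise", {
  set.seed(60)
  n <- 200
  cls <- factor(rep(1:3, length.out = n))
  inf <- data.frame(i1 = as.numeric(cls) + rnorm(n, 0, 0.4),
                    i2 = as.numeric(cls) * 2 + rnorm(n, 0, 0.8),
                    i3 = -as.numeric(cls) + rnorm(n, 0, 0.5))
  noise <- as.data.frame(matrix(runif(n * 10), n, 10))
  X <- normalize01(cbind(inf, noise))
  hits <- vapply(1:10, function(s) {
    sw <- threshold_sweep_select(X, cls, mode = "classify", n_seeds = 2,
                                 sweep_seeds = 1, master_seed = s)
    all(c("i1", "i2", "i3") %in% sw$selected)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("normalization maps to [0,1] and flags constant columns", {
  df <- data.frame(a = c(2, 4, 6), b = rep(5, 3))
  out <- normalize01(df)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, rep(0, 3))
  expect_identical(attr(out, "constant_cols"), "b")
})
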