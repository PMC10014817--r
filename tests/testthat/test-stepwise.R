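test_that("train/test split is seeded, sized by rounding, and reproducible", {
  s <- split_train_test(1:10, 0.7, seed = 3)
  expect_length(s$train, 7)
  expect_length(s$test, 3)
  expect_length(intersect(s$train, s$test), 0)

  s44 <- split_train_test(1:44, 0.7, seed = 8)
  expect_length(s44$train, 31)
  expect_length(s44$test, 13)

  expect_identical(split_train_test(1:44, 0.7, seed = 8), s44)
  expect_false(identical(split_train_test(1:44, 0.7, seed = 9), s44))
  expect_error(split_train_test(1:1), "at least 2")
})

test_that("predictor caps follow the documented rules", {
  expect_equal(max_predictors(31), 6L)
  expect_equal(max_predictors(23), 4L)
  expect_equal(max_predictors(120, "tabachnick_50_8m"), 8L)
  expect_error(max_predictors(50, "tabachnick_50_8m"), "no predictors")
  expect_error(max_predictors(4), "no predictors")
})

test_that("the default stage grouping partitions the 744-feature universe", {
  for (sc in c("HHS", "KSS_ks")) {
    grp <- stage_grouping(sc)
    expect_length(grp, 5)
    expect_equal(sum(lengths(grp)), 744)
    expect_length(unique(unlist(grp)), 744)
  }
  expect_true(all(grepl("hip", stage_grouping("HHS")$score_joint)))
  expect_true(all(grepl("knee", stage_grouping("KSS_ks")$score_joint)))
})

test_that("a dominant predictor is selected exactly, noise features are not", {
  withr::with_seed(42, {
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 51), n))
    names(X) <- c("x1", paste0("z", 1:50))
    y <- 3 * X$x1 + rnorm(n, 0, 1e-9)
    fit <- suppressWarnings(
      hierarchical_stepwise(X, y, names(X), max_predictors = 10))
    expect_identical(fit$selected, "x1")
    expect_equal(fit$coefficients$estimate, 3, tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-12)
  })
})

test_that("entry p-values match the augmented-model t test from lm", {
  withr::with_seed(7, {
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 4), n))
    names(X) <- paste0("f", 1:4)
    y <- 0.8 * X$f1 + rnorm(n)
    fit <- hierarchical_stepwise(X, y, names(X), p_enter = 0.9999,
                                 p_remove = 0.99999, max_predictors = 4)
    # first entry: the procedure's choice must equal the smallest lm p-value
    first <- fit$history$feature[fit$history$action == "enter"][1]
    pvals <- vapply(names(X), function(f) {
      summary(lm(y ~ X[[f]]))$coefficients[2, 4]
    }, numeric(1))
    expect_identical(first, names(which.min(pvals)))
    # refitting the final set from scratch reproduces the coefficients
    refit <- lm(y ~ ., data = cbind(X[, fit$selected, drop = FALSE], y = y))
    expect_equal(sort(unname(coef(refit)[-1])),
                 sort(fit$coefficients$estimate), tolerance = 1e-9)
    expect_equal(unname(coef(refit)[1]), fit$intercept, tolerance = 1e-9)
  })
})

test_that("single-stage selection respects an all-subsets oracle (<= 6 features)", {
  withr::with_seed(12, {
    n <- 80
    X <- as.data.frame(matrix(rnorm(n * 6), n))
    names(X) <- paste0("f", 1:6)
    y <- 1.5 * X$f1 - 1.0 * X$f3 + rnorm(n, 0, 0.8)
    fit <- hierarchical_stepwise(X, y, names(X), p_enter = 0.05,
                                 p_remove = 0.05, max_predictors = 6)
    # brute-force all subsets: adjusted R2 of the selected set must be within
    # the attainable range, and every retained predictor significant
    subsets <- unlist(lapply(0:6, function(k)
      utils::combn(names(X), k, simplify = FALSE)), recursive = FALSE)
    adj <- vapply(subsets, function(s) {
      if (!length(s)) return(0)
      summary(lm(y ~ ., data = cbind(X[, s, drop = FALSE], y = y)))$adj.r.squared
    }, numeric(1))
    sel_adj <- fit$adj_r_squared
    expect_gte(sel_adj, min(adj))
    expect_lte(sel_adj, max(adj) + 1e-12)
    expect_true(all(c("f1", "f3") %in% fit$selected))
    expect_true(all(fit$coefficients$p_value < 0.05))
  })
})

test_that("stage order is respected and cross-stage removal works", {
  withr::with_seed(3, {
    n <- 150
    x1 <- rnorm(n)
    x2 <- x1 + rnorm(n, 0, 0.15)   # stage-2 proxy that supersedes x1
    x3 <- rnorm(n)
    y <- 2 * x2 + 0.8 * x3 + rnorm(n, 0, 0.3)
    X <- data.frame(x1, x2, x3)
    grp <- list(a = "x1", b = c("x2", "x3"))
    fit <- hierarchical_stepwise(X, y, grp, max_predictors = 3)
    hist <- fit$history
    # x1 (stage a) entered before stage b opened
    expect_identical(hist$feature[hist$action == "enter"][1], "x1")
    # a feature never enters before its stage is opened
    enter_steps <- which(hist$action == "enter")
    first_b <- min(which(hist$feature %in% c("x2", "x3")))
    expect_gt(first_b, which(hist$feature == "x1")[1])
    # x1 removed once x2 (the better proxy) is in
    expect_true("x1" %in% hist$feature[hist$action == "remove"])
    expect_setequal(fit$selected, c("x2", "x3"))
  })
})

test_that("the predictor cap limits entries and the best compliant model wins", {
  withr::with_seed(21, {
    n <- 200
    X <- as.data.frame(matrix(rnorm(n * 8), n))
    names(X) <- paste0("f", 1:8)
    y <- rowSums(X[, 1:5]) + rnorm(n, 0, 0.2)
    fit <- hierarchical_stepwise(X, y, names(X), max_predictors = 3)
    expect_lte(length(fit$selected), 3)
    expect_true(all(fit$history$n_predictors <= 3))
  })
})

test_that("selection is deterministic and bit-reproducible", {
  withr::with_seed(5, {
    X <- as.data.frame(matrix(rnorm(100 * 10), 100))
    y <- X[[1]] + rnorm(100)
  })
  f1 <- hierarchical_stepwise(X, y, names(X), max_predictors = 5)
  f2 <- hierarchical_stepwise(X, y, names(X), max_predictors = 5)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 0)
})

test_that("degenerate inputs are handled: collinear and constant columns", {
  withr::with_seed(9, {
    n <- 50
    x1 <- rnorm(n)
    X <- data.frame(x1 = x1, dup = x1, const = 1, x2 = rnorm(n))
    y <- 2 * x1 + rnorm(n, 0, 0.4)
    expect_warning(
      fit <- hierarchical_stepwise(X, y, names(X), max_predictors = 3),
      "collinear")
    expect_true("x1" %in% fit$selected || "dup" %in% fit$selected)
    expect_false(all(c("x1", "dup") %in% fit$selected))
    expect_false("const" %in% fit$selected)
  })
})

test_that("k-fold CV: perfect fits give R2 = 1, pure noise gives <= 0 on average", {
  withr::with_seed(2, {
    n <- 60
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- 2 + 3 * X$a - X$b
    cv <- kfold_cv(X, y, c("a", "b"), k = 10, seed = 4)
    expect_equal(cv$folds$r_squared, rep(1, 10), tolerance = 1e-9)
    expect_equal(cv$mean_r_squared, 1, tolerance = 1e-9)
  })
  # determinism
  withr::with_seed(3, {
    X <- data.frame(a = rnorm(50)); y <- rnorm(50)
  })
  cv1 <- kfold_cv(X, y, "a", k = 10, seed = 6)
  cv2 <- kfold_cv(X, y, "a", k = 10, seed = 6)
  expect_identical(cv1$folds, cv2$folds)
  # fold sizes differ by at most one and partition the data
  expect_lte(diff(range(table(cv1$assignment))), 1)
  expect_length(cv1$assignment, 50)
  # independence: mean held-out R2 <= 0 in expectation (simulation oracle)
  ms <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      Xs <- data.frame(a = rnorm(40), b = rnorm(40))
      ys <- rnorm(40)
    })
    kfold_cv(Xs, ys, c("a", "b"), k = 5, seed = s)$mean_r_squared
  }, numeric(1))
  expect_lt(mean(ms), 0)
  # a fold whose training part has fewer than p + 2 cases is refused
  Xs <- data.frame(a = rnorm(6), b = rnorm(6), c = rnorm(6))
  expect_error(kfold_cv(Xs, rnorm(6), c("a", "b", "c"), k = 3),
               "smaller k")
})

test_that("diagnostics flag collinearity, outliers and heteroscedasticity", {
  withr::with_seed(31, {
    n <- 120
    # columns orthogonal to each other *and* to the intercept
    X <- as.data.frame(qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, -1])
    names(X) <- c("u", "v", "w")
    y <- X$u + 0.5 * X$v + rnorm(n, 0, 0.1)
    fit <- lm(y ~ ., data = cbind(X, y = y))
    d <- diagnostics(fit)
    expect_equal(d$vif$vif, rep(1, 3), tolerance = 1e-9)
    expect_false(any(d$vif$flag))

    # duplicated predictor: VIF explodes
    X2 <- data.frame(a = X$u, b = X$u + rnorm(n, 0, 1e-9), c = X$v)
    f2 <- lm(y ~ ., data = cbind(X2, y = y))
    d2 <- diagnostics(f2)
    expect_true(any(!is.finite(d2$vif$vif) | d2$vif$vif > 10))
    expect_true(any(d2$vif$flag))

    # planted outlier
    y3 <- y; y3[7] <- y3[7] + 5
    d3 <- diagnostics(lm(y3 ~ u + v + w, data = cbind(X, y3 = y3)))
    expect_true(d3$outliers$flag[7])
  })
  # heteroscedastic fixture: sigma proportional to x -> BP flag in >= 80/100
  flags <- vapply(1:100, function(s) {
    withr::with_seed(5000 + s, {
      x <- runif(200, 0.2, 3)
      yh <- 1 + x + rnorm(200, 0, 0.5 * x)
    })
    diagnostics(lm(yh ~ x))$breusch_pagan$flag
  }, logical(1))
  expect_gte(sum(flags), 80)
})
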