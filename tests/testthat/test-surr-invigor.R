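test_that("feature screening matches the hand-computed Welch t-test", {
  x <- cbind(f1 = c(1, 2, 3, 4, 5, 6))
  lab <- factor(c("slow", "slow", "slow", "fast", "fast", "fast"),
                levels = c("slow", "fast"))
  sc <- screen_features(x, lab, threshold_p = 0.2)
  # means 2 vs 5, both variances 1: t = -3 / sqrt(2/3), df = 4
  expect_equal(sc$table$t_statistic, -3 / sqrt(2 / 3))
  expect_equal(sc$table$df, 4)
  expect_equal(sc$table$p_value, 0.02131164, tolerance = 1e-6)
  expect_true(sc$table$admitted)
})

test_that("screening ranks, thresholds and excludes as specified", {
  set.seed(2)
  n <- 60
  lab <- factor(rep(c("slow", "fast"), each = n / 2),
                levels = c("slow", "fast"))
  x <- cbind(strong = rnorm(n) + 2 * (lab == "fast"),
             weak = rnorm(n) + 0.5 * (lab == "fast"),
             null = rnorm(n),
             flat = rep(1, n))
  sc <- screen_features(x, lab, threshold_p = 0.2)
  expect_equal(sc$excluded, "flat")
  expect_equal(sc$table$feature[1], "strong")
  expect_equal(sc$table$rank, 1:3)
  # identical distributions: t = 0, p = 1, not admitted
  x2b <- cbind(same = c(1, 2, 3, 1, 2, 3))
  lab2b <- factor(rep(c("slow", "fast"), each = 3),
                  levels = c("slow", "fast"))
  sc2 <- screen_features(x2b, lab2b, threshold_p = 0.2)
  expect_equal(sc2$table$t_statistic, 0)
  expect_equal(sc2$table$p_value, 1)
  expect_false(sc2$table$admitted)
  # threshold 1 admits every testable feature
  expect_true(all(screen_features(x, lab, threshold_p = 1)$table$admitted))
})

test_that("knn_predict matches the spec toys and a brute-force oracle", {
  model <- structure(list(
    algorithm = "knn", features = "f",
    k = 1L,
    standardisation = list(center = c(f = 0), scale = c(f = 1)),
    train_x = matrix(c(0, 1, 10), ncol = 1, dimnames = list(NULL, "f")),
    train_labels = factor(c("slow", "slow", "fast"),
                          levels = c("slow", "fast")),
    cv_accuracy = NA, seed = NA), class = "surrogate_model")
  expect_equal(as.character(knn_predict(model, c(f = 9))$labels), "fast")
  model$k <- 3L
  expect_equal(as.character(knn_predict(model, c(f = 9))$labels), "slow")
  model$k <- 1L
  expect_equal(as.character(knn_predict(model, c(f = 1))$labels), "slow")
  expect_error(knn_predict(model, matrix(1, 1, 1,
                                         dimnames = list(NULL, "g"))),
               "lacks feature")

  # brute-force oracle over random training sets and queries
  set.seed(13)
  for (rep_i in 1:4) {
    ntr <- 50; p <- 3; k <- c(1, 3, 5, 7)[rep_i]
    tr <- matrix(rnorm(ntr * p), ntr, p,
                 dimnames = list(NULL, paste0("f", 1:p)))
    lab <- factor(sample(c("slow", "fast"), ntr, replace = TRUE),
                  levels = c("slow", "fast"))
    st <- invigor:::.standardise_fit(tr)
    m <- structure(list(algorithm = "knn", features = colnames(tr), k = k,
                        standardisation = st,
                        train_x = invigor:::.standardise_apply(tr, st),
                        train_labels = lab, cv_accuracy = NA, seed = NA),
                   class = "surrogate_model")
    q <- matrix(rnorm(50 * p), 50, p, dimnames = list(NULL, colnames(tr)))
    got <- knn_predict(m, q)$labels
    qs <- invigor:::.standardise_apply(q, st)
    want <- vapply(seq_len(nrow(qs)), function(i) {
      d <- sqrt(colSums((t(m$train_x) - qs[i, ])^2))
      nn <- order(d)[seq_len(k)]
      names(which.max(table(lab[nn])))
    }, character(1))
    expect_equal(as.character(got), want)
  }
})

test_that("cross-validation is seeded, stratified and calibrated", {
  # perfectly separable clusters -> accuracy 1
  set.seed(4)
  n <- 80
  lab <- factor(rep(c("slow", "fast"), each = n / 2),
                levels = c("slow", "fast"))
  x <- cbind(f = rnorm(n, ifelse(lab == "fast", 10, -10)))
  cv <- cross_validate(x, lab, k = 3, repeats = 5, seed = 1)
  expect_equal(cv$mean_accuracy, 1)
  # identical seed -> identical per-repeat accuracies
  f <- make_null_fixture(100, seed = 6)
  cv1 <- cross_validate(f$x, f$labels, k = 5, repeats = 10, seed = 42)
  cv2 <- cross_validate(f$x, f$labels, k = 5, repeats = 10, seed = 42)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  # permuted labels, balanced classes: accuracy near 1/2
  fb <- make_selection_fixture(200, seed = 9)
  perm <- invigor:::with_seed(10, sample(fb$labels))
  cvp <- cross_validate(fb$x[, 1:3], perm, k = 9, repeats = 100, seed = 3)
  expect_lt(abs(cvp$mean_accuracy - 0.5), 0.08)
  # class smaller than fold count errors
  expect_error(cross_validate(x[1:6, , drop = FALSE],
                              lab[c(1:3, 41:43)], k = 1, folds = 5),
               "folds")
  # accuracy invariant to affine rescaling of a feature
  f2 <- make_selection_fixture(120, seed = 12)
  xa <- f2$x; xa[, 1] <- 100 * xa[, 1] - 7
  cva <- cross_validate(f2$x, f2$labels, k = 7, repeats = 5, seed = 8)
  cvb <- cross_validate(xa, f2$labels, k = 7, repeats = 5, seed = 8)
  expect_equal(cva$mean_accuracy, cvb$mean_accuracy)
})

test_that("sequential selection honours structure, ties and budget", {
  f <- make_selection_fixture(120, seed = 3)
  sc <- screen_features(f$x, f$labels)
  # single admitted feature -> only one-feature sets in the trace
  sc1 <- sc
  sc1$table$admitted <- sc1$table$rank == 1
  m1 <- sequential_select(f$x, f$labels, sc1, repeats = 3, seed = 5)
  expect_true(all(m1$trace$n_features == 1))
  expect_equal(length(m1$features), 1L)
  # budget must cover the zoo
  expect_error(sequential_select(f$x, f$labels, sc, budget = 0), "budget")
  # equal accuracies resolve to the smaller feature set
  m <- sequential_select(f$x, f$labels, sc, repeats = 3, seed = 5)
  best_acc <- max(m$trace$cv_accuracy)
  tied <- m$trace[m$trace$cv_accuracy == best_acc, ]
  expect_equal(length(m$features), min(tied$n_features))
  # identical seed reproduces trace and winner exactly
  m2 <- sequential_select(f$x, f$labels, sc, repeats = 3, seed = 5)
  expect_identical(m$trace, m2$trace)
  expect_identical(m$features, m2$features)
  expect_identical(m$k, m2$k)
})

test_that("the surrogate artifact survives JSON serialisation exactly", {
  f <- make_selection_fixture(100, seed = 17)
  sc <- screen_features(f$x, f$labels)
  m <- sequential_select(f$x, f$labels, sc, repeats = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  expect_equal(m2$features, m$features)
  expect_equal(m2$k, m$k)
  expect_equal(m2$train_x, m$train_x, ignore_attr = TRUE)
  q <- matrix(rnorm(60 * ncol(f$x)), 60,
              dimnames = list(NULL, colnames(f$x)))
  expect_identical(knn_predict(m, q[, m$features, drop = FALSE])$labels,
                   knn_predict(m2, q[, m2$features, drop = FALSE])$labels)
})

test_that("apply_surrogate predicts, reports and validates", {
  g <- generate_cohort(generator_config(n = 150, seed = 21))
  sm <- compute_sm_invigor(g$cohort, "sphere",
                           growth_spec("power", alpha = 0.5),
                           threshold = 0.045)
  fm <- surrogate_features(sm$cohort)
  labels <- droplevels(sm$cohort$growth_group[fm$rows])
  sc <- screen_features(fm$x, labels)
  model <- sequential_select(fm$x, labels, sc, repeats = 5, seed = 7)
  # resubstitution on the training cohort is self-consistent
  res <- apply_surrogate(model, sm$cohort)
  expect_equal(levels(res$cohort$surr_group), c("slow", "fast"))
  resub <- mean(res$cohort$surr_group == sm$cohort$growth_group,
                na.rm = TRUE)
  direct <- mean(knn_predict(model, fm$x)$labels == labels)
  expect_equal(resub, direct)
  expect_false(is.null(res$report))
  # a cohort without survival gives labels only
  df <- as.data.frame(g$cohort)
  df$bcss_months <- NA; df$event <- NA
  res2 <- apply_surrogate(model, as_cohort(df))
  expect_null(res2$report)
  expect_false(anyNA(res2$cohort$surr_group))
  # missing feature column is named in the error
  expect_error(surrogate_features(data.frame(grade = 1:3),
                                  features = c("grade", "npi")), "npi")
})
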