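# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default surrogate candidate features
#'
#' The screened clinicopathological variables: Ki67, mitotic score,
#' histological tumour size, NPI, grade, nodal stage and the mammographic
#' (diagnostic) tumour size.
#'
#' @return Character vector of feature column names (the mammographic size
#'   is the derived column \code{mammo_size_mm}).
#' @export
default_surrogate_features <- function() {
  c("ki67_percent", "mitotic_score", "histological_size_mm", "npi",
    "grade", "nodal_stage", "mammo_size_mm")
}

#' Extract a numeric feature matrix from a cohort
#'
#' Builds the patients x features matrix consumed by the surrogate stage.
#' The derived feature \code{mammo_size_mm} is the major diagnostic-mammogram
#' dimension.
#'
#' @param cohort A \code{cohort_table} (or labelled data frame).
#' @param features Feature column names (default
#'   \code{\link{default_surrogate_features}}).
#' @param complete_cases Drop rows with any missing feature (default TRUE).
#' @return A list: \code{x} (numeric matrix), \code{rows} (logical vector of
#'   retained rows in the input).
#' @export
surrogate_features <- function(cohort,
                               features = default_surrogate_features(),
                               complete_cases = TRUE) {
  df <- as.data.frame(cohort)
  if ("mammo_size_mm" %in% features && !"mammo_size_mm" %in% names(df)) {
    df$mammo_size_mm <- df$diag_dim_major
  }
  missing_cols <- setdiff(features, names(df))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(as.data.frame(lapply(df[features], as.numeric)))
  colnames(x) <- features
  rows <- rep(TRUE, nrow(x))
  if (complete_cases) rows <- stats::complete.cases(x)
  list(x = x[rows, , drop = FALSE], rows = rows)
}

#' Screen candidate surrogate features by Welch t-test
#'
#' Per feature, a two-tailed Welch (unequal-variance) two-sample t-test of
#' the mean difference between fast- and slow-growing tumours; features are
#' ranked by ascending p and admitted when p is below the threshold
#' (default 0.2, the screening band used before sequential selection).
#'
#' @param x Numeric patients x features matrix (named columns).
#' @param labels Factor with levels slow/fast (any two levels).
#' @param threshold_p Admission threshold on the p-value.
#' @return A \code{screening_result}: data frame \code{table} with columns
#'   feature, t_statistic, df, p_value, rank, admitted (ordered by rank);
#'   \code{excluded} names features untestable (zero variance in both
#'   groups, or a group with < 2 values).
#' @export
screen_features <- function(x, labels, threshold_p = 0.2) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  g <- factor(labels)
  if (nlevels(g) != 2L) stop("labels must have two levels", call. = FALSE)
  res <- list(); excluded <- character()
  for (f in colnames(x)) {
    a <- x[g == levels(g)[1L], f]; b <- x[g == levels(g)[2L], f]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::var(a) == 0 && stats::var(b) == 0)) {
      excluded <- c(excluded, f)
      next
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res[[f]] <- data.frame(feature = f,
                           t_statistic = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p_value = tt$p.value,
                           stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no testable features", call. = FALSE)
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$p_value), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$admitted <- tab$p_value < threshold_p
  rownames(tab) <- NULL
  structure(list(table = tab, excluded = excluded,
                 threshold_p = threshold_p),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d feature(s), %d admitted (p < %g)\n",
              nrow(x$table), sum(x$table$admitted), x$threshold_p))
  print(x$table, digits = 4)
  invisible(x)
}

# Standardisation learned on training data only.
.standardise_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}
.standardise_apply <- function(x, st) {
  sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/")
}

# Vectorised KNN: squared Euclidean distances of every query to every
# training point; per query the k nearest (ties by training order, which
# order() preserves for the radix sort) vote by majority. k odd avoids ties.
.knn_vote <- function(train_x, train_labels, query_x, k) {
  if (nrow(train_x) < k) stop("fewer training points than k", call. = FALSE)
  d2 <- outer(rowSums(query_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(query_x)), rowSums(train_x^2)) -
    2 * query_x %*% t(train_x)
  lv <- levels(train_labels)
  pred <- character(nrow(query_x))
  votes <- matrix(0L, nrow(query_x), length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(nrow(query_x))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(factor(train_labels[nn], levels = lv))
    votes[i, ] <- as.integer(tab)
    pred[i] <- lv[which.max(tab)]
  }
  list(labels = factor(pred, levels = lv), votes = votes)
}

#' Predict with a frozen KNN surrogate model
#'
#' Standardises the query with the parameters stored in the artifact (never
#' recomputed), takes Euclidean distances in the standardised space and
#' returns the majority vote over the k nearest training points. Distance
#' ties are broken by training-point order; odd k prevents vote ties.
#'
#' @param model A \code{surrogate_model} (from
#'   \code{\link{sequential_select}} or \code{\link{read_surrogate}}).
#' @param query Numeric matrix (or vector for one patient) carrying the
#'   model's features as columns, on the raw (unstandardised) scale.
#' @return A list: \code{labels} (factor slow/fast) and \code{votes}
#'   (neighbour counts per class).
#' @export
knn_predict <- function(model, query) {
  stopifnot(inherits(model, "surrogate_model"))
  if (is.null(dim(query))) {
    query <- matrix(query, nrow = 1,
                    dimnames = list(NULL, model$features))
  }
  missing_cols <- setdiff(model$features, colnames(query))
  if (length(missing_cols)) {
    stop("query lacks feature(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  q <- .standardise_apply(query[, model$features, drop = FALSE],
                          model$standardisation)
  .knn_vote(model$train_x, model$train_labels, q, model$k)
}

#' Repeated stratified cross-validated accuracy of a KNN configuration
#'
#' Stratified k-fold cross-validation, repeated: per repeat each class is
#' partitioned into folds at random, standardisation is fit on each training
#' fold only, and accuracy is the fraction of held-out patients whose
#' predicted label matches their given label. Fully reproducible from the
#' seed; the caller's RNG state is untouched.
#'
#' @param x Numeric patients x features matrix.
#' @param labels Two-level factor.
#' @param k KNN neighbour count (odd).
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 100, averaged).
#' @param seed Integer seed.
#' @return A list: \code{mean_accuracy}, \code{per_repeat} (vector of
#'   per-repeat mean accuracies).
#' @export
cross_validate <- function(x, labels, k, folds = 5, repeats = 100, seed = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(labels), k >= 1)
  g <- factor(labels)
  if (any(table(g) < folds)) {
    stop("each class needs at least `folds` members", call. = FALSE)
  }
  n <- nrow(x)
  per_repeat <- with_seed(seed, {
    vapply(seq_len(repeats), function(rep_i) {
      fold_id <- integer(n)
      for (lv in levels(g)) {
        idx <- which(g == lv)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f; te <- !tr
        st <- .standardise_fit(x[tr, , drop = FALSE])
        ktr <- min(k, sum(tr))
        pred <- .knn_vote(.standardise_apply(x[tr, , drop = FALSE], st),
                          g[tr],
                          .standardise_apply(x[te, , drop = FALSE], st),
                          ktr)
        correct <- correct + sum(pred$labels == g[te])
      }
      correct / n
    }, numeric(1))
  })
  list(mean_accuracy = mean(per_repeat), per_repeat = per_repeat)
}

# Cross-validated accuracy for a whole grid of k values in one pass:
# fold draws and neighbour orderings are shared across the grid, so the
# sweep is equivalent to scoring each k on the same folds. Two-class only.
.cv_knn_sweep <- function(x, labels, ks, folds, repeats, seed) {
  g <- factor(labels)
  n <- nrow(x)
  lv2 <- levels(g)[2L]
  correct <- with_seed(seed, {
    acc <- matrix(0, repeats, length(ks))
    for (rep_i in seq_len(repeats)) {
      fold_id <- integer(n)
      for (lv in levels(g)) {
        idx <- which(g == lv)
        fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      hits <- numeric(length(ks))
      for (f in seq_len(folds)) {
        tr <- fold_id != f; te <- !tr
        st <- .standardise_fit(x[tr, , drop = FALSE])
        tx <- .standardise_apply(x[tr, , drop = FALSE], st)
        qx <- .standardise_apply(x[te, , drop = FALSE], st)
        d2 <- outer(rowSums(qx^2), rep(1, nrow(tx))) +
          outer(rep(1, nrow(qx)), rowSums(tx^2)) - 2 * qx %*% t(tx)
        is2 <- g[tr] == lv2
        truth2 <- g[te] == lv2
        kcap <- pmin(ks, nrow(tx))
        for (i in seq_len(nrow(qx))) {
          cnt2 <- cumsum(is2[order(d2[i, ])])
          pred2 <- cnt2[kcap] * 2 > kcap
          hits <- hits + (pred2 == truth2[i])
        }
      }
      acc[rep_i, ] <- hits / n
    }
    acc
  })
  colMeans(correct)
}

#' Forward sequential feature selection with a budgeted KNN search
#'
#' Grows the feature set one feature at a time in screening-rank order
#' (admitted features only). At each set size, every hyperparameter
#' candidate of every algorithm in the zoo is scored by repeated stratified
#' cross-validation; the configuration with maximal mean CV accuracy wins,
#' with ties broken by fewer features, then zoo order, then the smaller k.
#' The hyperparameter search is a seeded exhaustive scan over odd k,
#' truncated at \code{budget} evaluations per (set, algorithm).
#'
#' @param x Numeric patients x features matrix (named columns).
#' @param labels Two-level factor (slow/fast).
#' @param screening A \code{screening_result} for these features.
#' @param zoo Algorithm list; only \code{"knn"} is shipped.
#' @param budget Maximum hyperparameter evaluations per feature set.
#' @param folds,repeats Cross-validation control.
#' @param seed Integer seed governing all CV fold draws.
#' @return A \code{surrogate_model}: algorithm, \code{features}, \code{k},
#'   \code{standardisation} (center/scale fit on all training rows),
#'   \code{train_x} (standardised), \code{train_labels},
#'   \code{cv_accuracy}, \code{seed}, and the full evaluation \code{trace}.
#' @export
sequential_select <- function(x, labels, screening, zoo = "knn",
                              budget = 180, folds = 5, repeats = 100,
                              seed = 1) {
  stopifnot(inherits(screening, "screening_result"))
  if (budget < length(zoo)) {
    stop("budget smaller than the algorithm zoo", call. = FALSE)
  }
  if (!all(zoo == "knn")) {
    stop("only the 'knn' algorithm is shipped", call. = FALSE)
  }
  admitted <- screening$table$feature[screening$table$admitted]
  admitted <- intersect(admitted, colnames(x))
  if (!length(admitted)) stop("no admitted features", call. = FALSE)
  g <- factor(labels)
  n <- nrow(x)
  k_grid <- seq(1, max(1, min(31, floor(n / 3))), by = 2)
  trace <- list()
  for (m in seq_along(admitted)) {
    feats <- admitted[seq_len(m)]
    xm <- x[, feats, drop = FALSE]
    ks <- k_grid[seq_len(min(length(k_grid), budget))]
    accs <- .cv_knn_sweep(xm, g, ks, folds = folds, repeats = repeats,
                          seed = seed + 7L * m)
    trace[[length(trace) + 1L]] <- data.frame(
      n_features = m, features = paste(feats, collapse = "+"),
      algorithm = "knn", k = ks, cv_accuracy = accs,
      stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, trace)
  # max accuracy; ties -> fewer features, then smaller k (zoo has one member)
  ord <- order(-trace$cv_accuracy, trace$n_features, trace$k)
  win <- trace[ord[1L], ]
  feats <- admitted[seq_len(win$n_features)]
  st <- .standardise_fit(x[, feats, drop = FALSE])
  structure(list(
    algorithm = "knn",
    features = feats,
    k = win$k,
    standardisation = st,
    train_x = .standardise_apply(x[, feats, drop = FALSE], st),
    train_labels = g,
    cv_accuracy = win$cv_accuracy,
    seed = seed,
    trace = trace
  ), class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "<surrogate_model> KNN (k = %d) on [%s]; CV accuracy = %.3f; n = %d\n",
    x$k, paste(x$features, collapse = ", "), x$cv_accuracy,
    nrow(x$train_x)))
  invisible(x)
}

#' Apply a surrogate model to a cohort
#'
#' Predicts fast/slow growth for every complete-case patient; when survival
#' columns are present and both predicted groups are populated, a KM /
#' log-rank / confounder-adjusted Cox report is produced.
#'
#' @param model A \code{surrogate_model}.
#' @param cohort A \code{cohort_table} carrying the model's features.
#' @param confounders Adjuster columns for the multivariate Cox fit
#'   (default grade, age, ER status); dropped from the fit when absent or
#'   constant.
#' @param horizon_months Horizon for the survival-percentage summary.
#' @return A list: \code{cohort} (with a \code{surr_group} column; NA where
#'   features were incomplete), \code{report} (or NULL when no survival).
#' @export
apply_surrogate <- function(model, cohort,
                            confounders = c("grade", "age_years",
                                            "er_status"),
                            horizon_months = 120) {
  stopifnot(inherits(model, "surrogate_model"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  fm <- surrogate_features(cohort, features = model$features)
  pred <- knn_predict(model, fm$x)
  out <- as.data.frame(cohort)
  out$surr_group <- factor(NA, levels = levels(pred$labels))
  out$surr_group[fm$rows] <- pred$labels
  report <- NULL
  has_surv <- all(c("bcss_months", "event") %in% names(out)) &&
    any(!is.na(out$bcss_months))
  if (has_surv) {
    ok <- !is.na(out$surr_group) & !is.na(out$bcss_months) &
      !is.na(out$event)
    gr <- droplevels(out$surr_group[ok])
    if (nlevels(gr) == 2) {
      tm <- out$bcss_months[ok]; ev <- out$event[ok]
      km <- km_estimate(tm, ev, out$surr_group[ok])
      surv_at <- vapply(levels(out$surr_group), function(lv) {
        km_survival_at(km[km$group == lv, ], horizon_months)
      }, numeric(1))
      adj <- intersect(confounders, names(out))
      adj <- adj[vapply(adj, function(a) {
        v <- out[[a]][ok]; length(unique(v[!is.na(v)])) > 1
      }, logical(1))]
      dat <- out[ok, , drop = FALSE]
      dat$surr_group <- droplevels(dat$surr_group)
      cox <- tryCatch({
        cc <- stats::complete.cases(dat[, c("surr_group", adj), drop = FALSE])
        covs <- dat[cc, c("surr_group", adj), drop = FALSE]
        covs[] <- lapply(covs, function(v) if (is.character(v)) factor(v) else v)
        fit_cox(dat$bcss_months[cc], dat$event[cc], covs)
      }, error = function(e) NULL)
      report <- list(km = km, survival_at_horizon = surv_at,
                     horizon_months = horizon_months,
                     logrank = logrank_test(tm, ev, out$surr_group[ok]),
                     cox_adjusted = cox)
    } else {
      warning("all predictions fall in one group; no group comparison",
              call. = FALSE)
    }
  }
  list(cohort = out, report = report)
}

#' Serialise / deserialise a surrogate model artifact
#'
#' Versioned JSON holding the selected features, standardisation
#' parameters, k, standardised training points, labels, CV accuracy and
#' seed; \code{read_surrogate(write_surrogate(m))} restores the model so
#' predictions are bit-identical.
#'
#' @param model A \code{surrogate_model}.
#' @param path Output path.
#' @return \code{path} invisibly (write); a \code{surrogate_model} (read).
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  payload <- list(
    format = "surrogate_model", version = "1.0",
    algorithm = model$algorithm,
    features = model$features,
    k = model$k,
    center = as.list(model$standardisation$center),
    scale = as.list(model$standardisation$scale),
    train_x = apply(model$train_x, 1, as.numeric, simplify = FALSE),
    train_labels = as.character(model$train_labels),
    label_levels = levels(model$train_labels),
    cv_accuracy = model$cv_accuracy,
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(p$format, "surrogate_model"))
  features <- unlist(p$features)
  train_x <- do.call(rbind, lapply(p$train_x,
                                   function(r) as.numeric(unlist(r))))
  colnames(train_x) <- features
  structure(list(
    algorithm = p$algorithm,
    features = features,
    k = as.integer(p$k),
    standardisation = list(center = unlist(p$center)[features],
                           scale = unlist(p$scale)[features]),
    train_x = train_x,
    train_labels = factor(unlist(p$train_labels),
                          levels = unlist(p$label_levels)),
    cv_accuracy = as.numeric(p$cv_accuracy),
    seed = p$seed,
    trace = NULL
  ), class = "surrogate_model")
}
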