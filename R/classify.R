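## Material-prediction experiment: repeated 70/30 holdout evaluation of a
## linear SVM, Gaussian naive Bayes and 2-means-as-classifier, with optional
## PCA reduction to 8 components, scored with five confusion-based measures.

MATERIAL_LEVELS <- c("barium", "water")

#' Holdout evaluation protocol
#'
#' @param n_iterations Number of repeated random holdout splits.
#' @param train_fraction Fraction of swallows assigned to training.
#' @param pca_components Number of principal components, or `NULL` for no
#'   reduction.
#' @param classifiers Subset of `svm_linear`, `naive_bayes`, `kmeans2`.
#' @param seed Seed governing all splits and classifier randomness.
#' @return An object of class `hrca_protocol`.
#' @export
eval_protocol <- function(n_iterations = 2000L, train_fraction = 0.70,
                          pca_components = 8L,
                          classifiers = c("svm_linear", "naive_bayes", "kmeans2"),
                          seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  classifiers <- match.arg(classifiers,
                           c("svm_linear", "naive_bayes", "kmeans2"),
                           several.ok = TRUE)
  structure(
    list(n_iterations = as.integer(n_iterations),
         train_fraction = train_fraction,
         pca_components = if (is.null(pca_components)) NULL else as.integer(pca_components),
         classifiers = classifiers, seed = seed),
    class = "hrca_protocol"
  )
}

#' Confusion counts for a two-material test split
#'
#' @param truth,predictions Factors/characters with barium/water labels.
#' @return Named list of the six counts used by [compute_performance()].
#' @export
confusion_counts <- function(truth, predictions) {
  truth <- factor(as.character(truth), levels = MATERIAL_LEVELS)
  predictions <- factor(as.character(predictions), levels = MATERIAL_LEVELS)
  list(correct_barium = sum(truth == "barium" & predictions == "barium"),
       total_barium_true = sum(truth == "barium"),
       correct_water = sum(truth == "water" & predictions == "water"),
       total_water_true = sum(truth == "water"),
       predicted_barium = sum(predictions == "barium"),
       predicted_water = sum(predictions == "water"))
}

#' Five performance measures from confusion counts
#'
#' Overall accuracy (correct classifications over all swallows), sensitivity
#' to barium and to water (correct material classifications over all true
#' swallows of that material), and barium and water predictive values
#' (correct material classifications over all classifications as that
#' material). A measure whose denominator is zero is undefined and returned
#' as `NA` (and excluded from iteration averages upstream).
#'
#' @param counts List as returned by [confusion_counts()].
#' @return Named numeric vector of the five measures, each in `[0, 1]`.
#' @export
compute_performance <- function(counts) {
  with(counts, {
    vals <- c(correct_barium, total_barium_true, correct_water,
              total_water_true, predicted_barium, predicted_water)
    if (any(vals < 0)) stopf("negative counts")
    if (correct_barium > min(total_barium_true, predicted_barium) ||
        correct_water > min(total_water_true, predicted_water)) {
      stopf("inconsistent confusion counts")
    }
    n <- total_barium_true + total_water_true
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    c(overall_accuracy = ratio(correct_barium + correct_water, n),
      sensitivity_barium = ratio(correct_barium, total_barium_true),
      sensitivity_water = ratio(correct_water, total_water_true),
      predictive_value_barium = ratio(correct_barium, predicted_barium),
      predictive_value_water = ratio(correct_water, predicted_water))
  })
}

#' Leak-free PCA reduction of a train/test pair
#'
#' Standardizes both splits with training means and SDs, fits principal
#' components on the training split only, and projects both splits onto the
#' first `k` components. The explained-variance fraction refers to the
#' training fit.
#'
#' @param train_X,test_X Numeric matrices with identical columns.
#' @param k Number of components (must not exceed the training rank).
#' @return List with `train_scores`, `test_scores`,
#'   `explained_variance_fraction`, and the `rotation` matrix.
#' @export
pca_reduce <- function(train_X, test_X, k) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (k > min(ncol(train_X), nrow(train_X))) {
    stopf("k (%d) exceeds feasible rank", k)
  }
  mu <- colMeans(train_X)
  sdv <- apply(train_X, 2, sd)
  sdv[sdv < .Machine$double.eps] <- 1
  tr <- sweep(sweep(train_X, 2, mu), 2, sdv, "/")
  te <- sweep(sweep(test_X, 2, mu), 2, sdv, "/")
  pc <- prcomp(tr, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (k > rank) stopf("k (%d) exceeds the rank of the training data (%d)", k, rank)
  list(train_scores = tr %*% pc$rotation[, seq_len(k), drop = FALSE],
       test_scores = te %*% pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance_fraction = sum(ev[seq_len(k)]) / sum(ev),
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}

#' 2-means clustering used as a classifier
#'
#' Fits 2-means to the training features (multiple restarts), labels each
#' cluster by the majority training label (ties go to the first material
#' level, barium), and labels test points by the nearest centroid. If the
#' training points are degenerate (identical), a single-cluster fallback
#' predicts the majority training label everywhere.
#'
#' @param train_X,test_X Numeric matrices.
#' @param train_labels Training material labels.
#' @param nstart Number of random restarts.
#' @return Factor of test predictions with barium/water levels.
#' @export
kmeans_classify <- function(train_X, train_labels, test_X, nstart = 5L) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  train_labels <- factor(as.character(train_labels), levels = MATERIAL_LEVELS)
  if (nlevels(droplevels(train_labels)) < 2L) {
    stopf("both materials must be present in the training data")
  }
  km <- tryCatch(kmeans(train_X, centers = 2L, nstart = nstart),
                 error = function(e) NULL)
  if (is.null(km)) {
    maj <- MATERIAL_LEVELS[which.max(tabulate(train_labels, 2L))]
    return(factor(rep(maj, nrow(test_X)), levels = MATERIAL_LEVELS))
  }
  cluster_label <- vapply(1:2, function(cl) {
    tab <- tabulate(train_labels[km$cluster == cl], 2L)
    MATERIAL_LEVELS[which.max(tab)]  # tie -> first level (barium)
  }, character(1))
  d <- vapply(1:2, function(cl) {
    rowSums(sweep(test_X, 2, km$centers[cl, ])^2)
  }, numeric(nrow(test_X)))
  d <- matrix(d, nrow = nrow(test_X))
  nearest <- max.col(-d, ties.method = "first")
  factor(cluster_label[nearest], levels = MATERIAL_LEVELS)
}

fit_and_predict <- function(classifier, train_X, train_y, test_X) {
  switch(classifier,
    svm_linear = {
      fit <- e1071::svm(train_X, train_y, kernel = "linear", cost = 1,
                        scale = FALSE)
      predict(fit, test_X)
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(train_X, train_y)
      predict(fit, test_X)
    },
    kmeans2 = kmeans_classify(train_X, train_y, test_X),
    stopf("unknown classifier: %s", classifier)
  )
}

#' Repeated 70/30 holdout evaluation
#'
#' For each iteration: a uniform random split at the swallow level (no
#' stratification, no participant grouping -- participants can appear in
#' both splits, deliberately mirroring a swallow-level protocol),
#' training-statistics standardization, optional leak-free PCA, then each
#' classifier is fit on the training split and scored on the test split
#' with the five measures of [compute_performance()]. Splits in which a
#' material is absent from the training data are redrawn (counted in the
#' report). Measures undefined in an iteration (empty predicted class) are
#' excluded from that measure's average, with a logged count. Rows with any
#' missing feature are dropped before evaluation.
#'
#' @param table Feature table.
#' @param protocol An [eval_protocol()].
#' @param return_iterations Keep the per-iteration measure array (for
#'   diagnostics/tests).
#' @return An object of class `hrca_performance`: per-classifier means and
#'   SDs of the five measures, mean PCA explained-variance fraction (when
#'   PCA is on), and bookkeeping counts.
#' @export
holdout_evaluate <- function(table, protocol = eval_protocol(),
                             return_iterations = FALSE) {
  feat_cols <- setdiff(names(table), KEY_COLUMNS)
  X_all <- as.matrix(table[, feat_cols, drop = FALSE])
  complete <- stats::complete.cases(X_all)
  n_dropped <- sum(!complete)
  X_all <- X_all[complete, , drop = FALSE]
  y_all <- factor(as.character(table$material[complete]),
                  levels = MATERIAL_LEVELS)
  n <- nrow(X_all)
  if (min(tabulate(y_all, 2L)) < 10L) {
    stopf("need at least 10 swallows per material")
  }
  n_train <- min(n - 1L, max(2L, round(protocol$train_fraction * n)))
  k <- protocol$pca_components
  metrics <- c("overall_accuracy", "sensitivity_barium", "sensitivity_water",
               "predictive_value_barium", "predictive_value_water")

  with_local_seed(protocol$seed, {
    iter_vals <- array(NA_real_,
                       dim = c(protocol$n_iterations, length(protocol$classifiers),
                               length(metrics)),
                       dimnames = list(NULL, protocol$classifiers, metrics))
    ev_frac <- numeric(0)
    n_redrawn <- 0L
    for (it in seq_len(protocol$n_iterations)) {
      repeat {
        idx <- sample.int(n, n_train)
        if (length(unique(y_all[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L
      }
      tr_X <- X_all[idx, , drop = FALSE]
      te_X <- X_all[-idx, , drop = FALSE]
      tr_y <- y_all[idx]
      te_y <- y_all[-idx]
      if (is.null(k)) {
        mu <- colMeans(tr_X)
        sdv <- apply(tr_X, 2, sd)
        sdv[sdv < .Machine$double.eps] <- 1
        tr_S <- sweep(sweep(tr_X, 2, mu), 2, sdv, "/")
        te_S <- sweep(sweep(te_X, 2, mu), 2, sdv, "/")
      } else {
        red <- pca_reduce(tr_X, te_X, k)
        tr_S <- red$train_scores
        te_S <- red$test_scores
        ev_frac <- c(ev_frac, red$explained_variance_fraction)
      }
      for (ci in seq_along(protocol$classifiers)) {
        pred <- fit_and_predict(protocol$classifiers[ci], tr_S, tr_y, te_S)
        iter_vals[it, ci, ] <-
          compute_performance(confusion_counts(te_y, pred))[metrics]
      }
    }
    summarize_one <- function(ci) {
      m <- iter_vals[, ci, , drop = FALSE]
      means <- apply(m, 3, mean, na.rm = TRUE)
      sds <- apply(m, 3, sd, na.rm = TRUE)
      und <- apply(m, 3, function(v) sum(is.na(v)))
      df <- data.frame(classifier = protocol$classifiers[ci],
                       t(means), stringsAsFactors = FALSE)
      names(df)[-1] <- metrics
      for (j in seq_along(metrics)) {
        df[[paste0(metrics[j], "_sd")]] <- sds[j]
        df[[paste0(metrics[j], "_n_undefined")]] <- und[j]
      }
      df
    }
    results <- do.call(rbind, lapply(seq_along(protocol$classifiers),
                                     summarize_one))
    rownames(results) <- NULL
    structure(
      list(results = results,
           space = if (is.null(k)) "raw" else "pca",
           pca_components = k,
           mean_explained_variance = if (length(ev_frac)) mean(ev_frac) else NA_real_,
           n_iterations = protocol$n_iterations,
           n_redrawn = n_redrawn,
           n_dropped_rows = n_dropped,
           iterations = if (return_iterations) iter_vals else NULL),
      class = "hrca_performance"
    )
  })
}

#' @export
print.hrca_performance <- function(x, ...) {
  cat(sprintf("<hrca_performance> %s space, %d iterations%s\n",
              x$space, x$n_iterations,
              if (x$space == "pca")
                sprintf(", mean PCA explained variance %.1f%%",
                        100 * x$mean_explained_variance) else ""))
  cols <- c("classifier", "overall_accuracy", "sensitivity_barium",
            "sensitivity_water", "predictive_value_barium",
            "predictive_value_water")
  print(x$results[, cols], row.names = FALSE, digits = 3)
  invisible(x)
}
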