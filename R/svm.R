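# Three-class C-SVC with RBF kernel on selected subband-entropy features:
# one-vs-one decomposition, per-feature standardisation learned on the
# training set, seeded stratified cross-validation for the (C, gamma) grid.

.svm_matrix <- function(features, bands) {
  missing <- setdiff(bands, names(features))
  if (length(missing)) {
    stop("feature table lacks band column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  as.matrix(features[, bands, drop = FALSE])
}

#' Train an RBF support-vector classifier on subband entropy features
#'
#' Fits a soft-margin C-SVC (one-vs-one for three classes) with kernel
#' `k(x, x') = exp(-gamma * ||x - x'||^2)` on the selected band columns.
#' Features are standardised with training-set mean and SD (stored in the
#' model, since the RBF kernel is scale-sensitive). Rows containing
#' undefined (`NA`) feature cells are rejected by default.
#'
#' The clinically tuned defaults are `C = 0.25`, `gamma = 0.0625`.
#'
#' @param features Wide feature table with `group` and band columns.
#' @param bands Band keys to use; a `feature_selection` object, character
#'   vector, or `NULL` for all band columns.
#' @param C Penalty parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param kernel `"rbf"` (default), `"polynomial"` or `"sigmoid"`.
#' @param na_policy `"reject"` (error on NA cells) or `"drop_rows"`.
#' @return A `wpse_svm` model object.
#' @export
svm_train <- function(features, bands = NULL, C = 0.25, gamma = 0.0625,
                      kernel = c("rbf", "polynomial", "sigmoid"),
                      na_policy = c("reject", "drop_rows")) {
  kernel <- match.arg(kernel)
  na_policy <- match.arg(na_policy)
  stopifnot(C > 0, gamma > 0)
  if (inherits(bands, "feature_selection")) bands <- bands$selected$band
  if (is.null(bands)) bands <- feature_bands(features)
  x <- .svm_matrix(features, bands)
  y <- factor(features$group)
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  bad <- which(rowSums(is.na(x)) > 0L)
  if (length(bad)) {
    if (na_policy == "reject") {
      stop("undefined feature cells in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    x <- x[-bad, , drop = FALSE]
    y <- droplevels(y[-bad])
  }
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  fit <- e1071::svm(xs, y, type = "C-classification",
                    kernel = if (kernel == "rbf") "radial" else kernel,
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, bands = bands, classes = levels(y),
                 center = center, scale = scl, C = C, gamma = gamma,
                 kernel = kernel),
            class = "wpse_svm")
}

#' @export
print.wpse_svm <- function(x, ...) {
  cat("<wpse_svm> ", x$kernel, " C-SVC: ", length(x$classes), " classes, ",
      length(x$bands), " bands, C = ", x$C, ", gamma = ", x$gamma,
      ", ", nrow(x$fit$SV), " SVs\n", sep = "")
  invisible(x)
}

#' Predict group labels for new feature rows
#'
#' Band columns are matched by name; a table missing any of the model's
#' bands is refused, and column order in `newdata` is irrelevant.
#'
#' @param object A `wpse_svm` model.
#' @param newdata Feature table containing the model's band columns.
#' @param ... Unused.
#' @return Factor of predicted group labels.
#' @export
predict.wpse_svm <- function(object, newdata, ...) {
  x <- .svm_matrix(newdata, object$bands)
  xs <- scale(x, center = object$center, scale = object$scale)
  unname(predict(object$fit, xs))
}

#' Evaluate a trained classifier on labelled features
#'
#' @param model A `wpse_svm` (or `wpse_svm_restored`) model.
#' @param features Labelled feature table (`group` + band columns).
#' @return An `svm_eval` object: `confusion` (truth x predicted counts),
#'   `per_class` accuracy (row-wise recall), `overall` accuracy.
#' @export
svm_evaluate <- function(model, features) {
  pred <- predict(model, features)
  truth <- factor(features$group, levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  confusion <- table(truth = truth, predicted = pred)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1L)
  overall <- sum(diag(confusion)) / sum(confusion)
  structure(list(confusion = confusion, per_class = per_class,
                 overall = overall),
            class = "svm_eval")
}

#' @export
print.svm_eval <- function(x, ...) {
  cat("<svm_eval> overall accuracy ", sprintf("%.1f%%", 100 * x$overall),
      "\n", sep = "")
  for (cl in names(x$per_class)) {
    cat("  ", cl, ": ", sprintf("%.1f%%", 100 * x$per_class[cl]), "\n",
        sep = "")
  }
  print(x$confusion)
  invisible(x)
}

#' @rdname svm_evaluate
#' @param x An `svm_eval`.
#' @param ... Unused.
#' @export
tidy.svm_eval <- function(x, ...) {
  tibble::tibble(class = names(x$per_class),
                 accuracy = unname(x$per_class),
                 n = unname(rowSums(x$confusion)))
}

#' @rdname svm_evaluate
#' @export
glance.svm_eval <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall, n = sum(x$confusion))
}

#' @rdname svm_train
#' @param x A `wpse_svm`.
#' @param ... Unused.
#' @export
glance.wpse_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, C = x$C, gamma = x$gamma,
                 n_bands = length(x$bands), n_classes = length(x$classes),
                 n_support = nrow(x$fit$SV))
}

# deterministic stratified fold assignment
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop("class '", cl, "' has fewer samples (", length(idx),
             ") than cv_folds = ", k, call. = FALSE)
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified cross-validated accuracy at fixed hyperparameters
#'
#' When `screen` is supplied, the band selection is re-run inside every
#' training fold (compare groups, keep bands with p below `screen$alpha`)
#' and the held-out fold is predicted from the fold's own selection. This
#' keeps the feature screen out of the test data: screening once on the
#' full table and then cross-validating the classifier alone looks far
#' better than chance even on label-free data, because the screen has
#' already seen the held-out subjects.
#'
#' @param features Labelled feature table.
#' @param bands Band keys (as in [svm_train()]); ignored when `screen`
#'   is given.
#' @param C,gamma Hyperparameters.
#' @param folds Number of stratified folds.
#' @param seed Seed controlling fold assignment.
#' @param kernel Kernel name.
#' @param screen Optional list with elements `method`, `alpha`,
#'   `correction` enabling fold-internal band selection; folds whose
#'   screen selects nothing fall back to all bands.
#' @return List: `accuracy` (pooled over held-out folds), `confusion`,
#'   `per_class`, `folds`, `predictions` tibble.
#' @export
svm_cv <- function(features, bands = NULL, C = 0.25, gamma = 0.0625,
                   folds = 5, seed = 1L, kernel = "rbf", screen = NULL) {
  if (inherits(bands, "feature_selection")) bands <- bands$selected$band
  if (is.null(bands)) bands <- feature_bands(features)
  y <- factor(features$group)
  fold <- .stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, nrow(features)), levels = levels(y))
  for (f in seq_len(folds)) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    train_tbl <- features[train_idx, , drop = FALSE]
    fold_bands <- bands
    if (!is.null(screen)) {
      sel <- select_features(
        compare_groups(train_tbl, method = screen$method %||% "anova"),
        alpha = screen$alpha %||% 0.05,
        correction = screen$correction %||% "none"
      )
      fold_bands <- if (sel$n_selected > 0) sel$selected$band
                    else feature_bands(features)
    }
    model <- svm_train(train_tbl, bands = fold_bands,
                       C = C, gamma = gamma, kernel = kernel)
    pred[test_idx] <- predict(model, features[test_idx, , drop = FALSE])
  }
  confusion <- table(truth = y, predicted = pred)
  list(accuracy = mean(pred == y),
       per_class = diag(confusion) / pmax(rowSums(confusion), 1L),
       confusion = confusion, folds = folds,
       predictions = tibble::tibble(subject_id = features$subject_id,
                                    truth = as.character(y),
                                    predicted = as.character(pred),
                                    fold = fold))
}

#' Grid search for (C, gamma) by stratified cross-validation
#'
#' Evaluates every grid point with the same seeded fold assignment and
#' returns the point with the highest CV accuracy; ties are broken toward
#' the smallest `C`, then the smallest `gamma`, so the result is fully
#' deterministic given the seed.
#'
#' @inheritParams svm_cv
#' @param C_grid,gamma_grid Candidate values (default powers of two,
#'   `2^-8 .. 2^8`).
#' @return List: `best_C`, `best_gamma`, `cv_accuracy`, and the full
#'   `grid` tibble (`C`, `gamma`, `accuracy`).
#' @export
svm_grid_search <- function(features, bands = NULL, C_grid = 2^(-8:8),
                            gamma_grid = 2^(-8:8), folds = 5, seed = 1L,
                            kernel = "rbf") {
  grid <- tidyr::expand_grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$accuracy <- purrr::map2_dbl(grid$C, grid$gamma, function(C, g) {
    svm_cv(features, bands = bands, C = C, gamma = g, folds = folds,
           seed = seed, kernel = kernel)$accuracy
  })
  ord <- order(-grid$accuracy, grid$C, grid$gamma)
  best <- grid[ord[1L], ]
  list(best_C = best$C, best_gamma = best$gamma,
       cv_accuracy = best$accuracy, grid = grid)
}
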