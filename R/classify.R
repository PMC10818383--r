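## Leave-one-subject-out supervised classification of MMG events.
##
## Three classifier families: radial-basis SVM (e1071), random forest
## (ranger) and linear discriminant analysis (MASS). Class imbalance is
## handled with balanced class weights (inverse class frequency; uniform
## priors for LDA). Features are standardized with training-fold
## mean/SD for SVM and LDA and passed raw to the forest. Hyperparameters
## are drawn by random search and scored by an inner LOSO loop over the
## training subjects only; they are tuned on the 3-class problem and
## reused for the 2-class problem.

#' Balanced accuracy
#'
#' Mean of the per-class recalls over the classes present in the truth
#' vector; robust to class imbalance (a constant prediction on a balanced
#' two-class problem scores 0.5).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 2)) # (0.5 + 1 + 1)/3
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  mean(vapply(classes, function(k) mean(y_pred[y_true == k] == k),
              numeric(1)))
}

balanced_case_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

#' Draw random hyperparameter settings
#'
#' Sampling distributions for the random search: SVM `C` and `gamma`
#' log-uniform on \[1e-3, 1e3\]; random forest `min_samples_split` in
#' 2..20, `min_samples_leaf` in 1..10, `max_depth` in 3..30 or unlimited
#' (0), `max_samples` uniform on \[0.3, 1\]; LDA `solver` in
#' {moment, mle}, `tol` log-uniform on \[1e-6, 1e-2\], `n_components` in
#' {1, K-1} (recorded for completeness; it affects the discriminant
#' projection, not the class prediction).
#'
#' @param model_family `"SVM"`, `"RF"` or `"LDA"`.
#' @param n Number of settings.
#' @param seed Integer seed.
#' @return Tibble of `n` parameter settings.
#' @export
sample_hyperparameters <- function(model_family, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  switch(model_family,
         SVM = tibble(C = 10^runif(n, -3, 3),
                      gamma = 10^runif(n, -3, 3)),
         RF = tibble(min_samples_split = sample(2:20, n, replace = TRUE),
                     min_samples_leaf = sample(1:10, n, replace = TRUE),
                     max_depth = sample(c(3:30, 0L), n, replace = TRUE),
                     max_samples = runif(n, 0.3, 1)),
         LDA = tibble(solver = sample(c("moment", "mle"), n, replace = TRUE),
                      tol = 10^runif(n, -6, -2),
                      n_components = sample(1:2, n, replace = TRUE)),
         stop("unknown model family: ", model_family, call. = FALSE))
}

default_hyperparameters <- function(model_family) {
  switch(model_family,
         SVM = tibble(C = 1, gamma = NA_real_), # NA: e1071 default 1/p
         RF = tibble(min_samples_split = 2L, min_samples_leaf = 1L,
                     max_depth = 0L, max_samples = 1),
         LDA = tibble(solver = "moment", tol = 1e-4, n_components = 2L))
}

fit_classifier <- function(x, y, model_family, params, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  scaled <- model_family %in% c("SVM", "LDA")
  center <- scale_sd <- NULL
  if (scaled) {
    center <- colMeans(x)
    scale_sd <- apply(x, 2, sd)
    scale_sd[scale_sd == 0 | is.na(scale_sd)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_sd, "/")
  }
  fit <- switch(
    model_family,
    SVM = {
      w <- length(y) / (nlevels(y) * table(y))
      gam <- if (is.na(params$gamma)) 1 / ncol(x) else params$gamma
      e1071::svm(x, y, kernel = "radial", cost = params$C, gamma = gam,
                 class.weights = stats::setNames(as.numeric(w), names(w)),
                 scale = FALSE)
    },
    RF = ranger::ranger(
      x = x, y = y, num.trees = 100,
      min.node.size = params$min_samples_split,
      min.bucket = params$min_samples_leaf,
      max.depth = params$max_depth,
      sample.fraction = params$max_samples,
      case.weights = balanced_case_weights(y),
      seed = seed, num.threads = 1),
    LDA = MASS::lda(x, grouping = y, prior = rep(1 / nlevels(y), nlevels(y)),
                    tol = params$tol, method = params$solver),
    stop("unknown model family: ", model_family, call. = FALSE))
  structure(list(fit = fit, family = model_family, center = center,
                 scale = scale_sd, levels = levels(y)),
            class = "tscs_classifier")
}

#' @export
predict.tscs_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- switch(object$family,
                SVM = as.character(predict(object$fit, x)),
                RF = as.character(predict(object$fit, data = x,
                                          num.threads = 1)$predictions),
                LDA = as.character(predict(object$fit, x)$class))
  out
}

inner_loso_score <- function(x, y, subjects, model_family, params, seed) {
  subj <- unique(subjects)
  scores <- vapply(subj, function(s) {
    tr <- subjects != s
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], model_family,
                          params, seed = seed)
    balanced_accuracy(y[!tr], predict(fit, x[!tr, , drop = FALSE]))
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Random hyperparameter search on training subjects
#'
#' Samples `n_iter` settings from the documented distributions and scores
#' each by mean balanced accuracy in an inner LOSO loop over the training
#' subjects (the outer test subject must already be excluded). Returns
#' the argmax setting.
#'
#' @param x Feature matrix / tibble of the training subjects.
#' @param y Labels (tuning is conventionally done on the 3-class labels).
#' @param subjects Subject id per row.
#' @param model_family `"SVM"`, `"RF"` or `"LDA"`.
#' @param n_iter Number of sampled settings (>= 1).
#' @param seed Integer seed; the same seed reproduces the chosen setting.
#' @return List with `params` (one-row tibble) and `scores` (tibble of
#'   all settings with their inner mean balanced accuracy).
#' @export
tune_hyperparameters <- function(x, y, subjects, model_family,
                                 n_iter = 50, seed = 1L) {
  stopifnot(n_iter >= 1)
  grid <- sample_hyperparameters(model_family, n_iter, seed = seed)
  grid$score <- vapply(seq_len(n_iter), function(i) {
    inner_loso_score(x, y, subjects, model_family, grid[i, ], seed = seed)
  }, numeric(1))
  list(params = grid[which.max(grid$score), , drop = FALSE],
       scores = grid)
}

#' Leave-one-subject-out cross-validation
#'
#' Each subject's events form one test fold for a model trained on all
#' remaining subjects; feature standardization and (optionally) the
#' random hyperparameter search see training folds only. When
#' `tune_labels` is supplied (typically the 3-class labels while `labels`
#' are 2-class), the search is run against those labels and the chosen
#' setting reused.
#'
#' @param x Feature matrix or tibble (rows = events).
#' @param labels Event labels.
#' @param subjects Subject id per row (>= 2 distinct).
#' @param model_family `"SVM"`, `"RF"` or `"LDA"`.
#' @param search_iterations Random-search iterations per fold; 0 uses the
#'   documented default setting without tuning.
#' @param tune_labels Labels used by the hyperparameter search (defaults
#'   to `labels`).
#' @param keys Optional tibble of per-row keys carried into the fold
#'   predictions.
#' @param seed Integer seed.
#' @return A `tscs_loso` object; see [tidy.tscs_loso()],
#'   [glance.tscs_loso()], [autoplot.tscs_loso()].
#' @export
loso_cross_validate <- function(x, labels, subjects, model_family = "RF",
                                search_iterations = 0, tune_labels = labels,
                                keys = NULL, seed = 1L) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(labels), length(labels) == length(subjects))
  subj <- unique(subjects)
  stopifnot(length(subj) >= 2)
  classes <- sort(unique(as.character(labels)))
  folds <- list()
  for (s in subj) {
    te <- subjects == s
    if (!any(te)) next
    tr <- !te
    params <- if (search_iterations >= 1) {
      tune_hyperparameters(x[tr, , drop = FALSE], tune_labels[tr],
                           subjects[tr], model_family,
                           n_iter = search_iterations, seed = seed)$params
    } else {
      default_hyperparameters(model_family)
    }
    fit <- fit_classifier(x[tr, , drop = FALSE], labels[tr], model_family,
                          params, seed = seed)
    pred <- predict(fit, x[te, , drop = FALSE])
    truth <- as.character(labels[te])
    cm <- table(factor(truth, levels = classes),
                factor(pred, levels = classes))
    pred_tbl <- tibble(truth = truth, pred = pred)
    if (!is.null(keys)) pred_tbl <- bind_cols(keys[te, , drop = FALSE],
                                              pred_tbl)
    folds[[s]] <- tibble(
      subject_id = s,
      n_test = sum(te),
      balanced_accuracy = balanced_accuracy(truth, pred),
      params = list(params),
      confusion = list(unclass(cm)),
      predictions = list(pred_tbl))
  }
  structure(list(folds = bind_rows(folds),
                 classes = classes,
                 model_family = model_family,
                 search_iterations = search_iterations,
                 seed = seed),
            class = "tscs_loso")
}

#' @export
print.tscs_loso <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "tscs_loso %s: %d folds, balanced accuracy %.3f +/- %.3f\n",
    x$model_family, g$n_subjects, g$mean_balanced_accuracy,
    g$sd_balanced_accuracy))
  invisible(x)
}

#' Per-fold results of a LOSO experiment
#'
#' @param x A `tscs_loso` object.
#' @param ... Unused.
#' @return Tibble with one row per test subject: `subject_id`, `n_test`,
#'   `balanced_accuracy`.
#' @method tidy tscs_loso
#' @export
tidy.tscs_loso <- function(x, ...) {
  x$folds %>% select("subject_id", "n_test", "balanced_accuracy")
}

#' One-row summary of a LOSO experiment
#'
#' Mean and standard deviation of the balanced accuracy across subjects.
#'
#' @param x A `tscs_loso` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance tscs_loso
#' @export
glance.tscs_loso <- function(x, ...) {
  ba <- x$folds$balanced_accuracy
  tibble(n_subjects = nrow(x$folds),
         mean_balanced_accuracy = mean(ba),
         sd_balanced_accuracy = if (length(ba) > 1) sd(ba) else 0,
         model_family = x$model_family)
}

#' Summed and row-normalized confusion matrices
#'
#' @param x A `tscs_loso` object.
#' @return List with `summed` (counts over all subjects) and `row_ratio`
#'   (each row of ground truth normalized to sum 1; rows with no events
#'   are `NaN`).
#' @export
confusion_matrices <- function(x) {
  stopifnot(inherits(x, "tscs_loso"))
  summed <- Reduce(`+`, x$folds$confusion)
  row_ratio <- sweep(summed, 1, rowSums(summed), "/")
  list(summed = summed, row_ratio = row_ratio)
}

#' Plot the summed confusion matrix of a LOSO experiment
#'
#' @param object A `tscs_loso` object.
#' @param normalize Plot row ratios instead of counts.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tscs_loso
#' @export
autoplot.tscs_loso <- function(object, normalize = FALSE, ...) {
  cm <- confusion_matrices(object)
  m <- if (normalize) cm$row_ratio else cm$summed
  df <- as.data.frame(as.table(m))
  names(df) <- c("truth", "prediction", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$value)
      else .data$value)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "ground truth class",
                  fill = if (normalize) "ratio" else "events") +
    ggplot2::theme_minimal()
}
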