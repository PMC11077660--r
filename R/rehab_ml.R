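#' Assemble the 8-D bilateral gait feature matrix
#'
#' One row per matched left/right cycle pair, columns in the fixed order
#' `l_maxaa, l_minaa, l_maxvel, l_gcd, r_maxaa, r_minaa, r_maxvel, r_gcd`
#' (maximum/minimum ankle angle in degrees, maximum dorsiflexion angular
#' velocity in deg/s, gait cycle duration in seconds, for each foot).
#' Cycles are paired by `cycle_index`; unpaired trailing cycles are dropped
#' with a logged count.
#'
#' @param left,right non-empty `"gait_features"` frames from
#'   [segment_gait()].
#' @param label class label attached to every row.
#' @return a data frame of class `"feature_matrix"` with the 8 feature
#'   columns plus `label`.
#' @export
build_features <- function(left, right, label) {
  if (!nrow(left) || !nrow(right))
    stop("both feature sequences must be non-empty", call. = FALSE)
  n <- min(nrow(left), nrow(right))
  dropped <- nrow(left) + nrow(right) - 2 * n
  if (dropped > 0)
    log_line("build_features: dropped %d unpaired trailing cycle(s)",
             dropped)
  l <- left[seq_len(n), ]
  r <- right[seq_len(n), ]
  out <- data.frame(
    l_maxaa = l$maxaa, l_minaa = l$minaa, l_maxvel = l$max_ang_vel,
    l_gcd = l$gcd,
    r_maxaa = r$maxaa, r_minaa = r$minaa, r_maxvel = r$max_ang_vel,
    r_gcd = r$gcd,
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE)
  structure(out, class = c("feature_matrix", "data.frame"))
}

FEATURE_COLUMNS <- c("l_maxaa", "l_minaa", "l_maxvel", "l_gcd",
                     "r_maxaa", "r_minaa", "r_maxvel", "r_gcd")

#' Read / write a feature matrix as CSV
#'
#' The column order is part of the schema; a stored matrix whose columns are
#' permuted or renamed is rejected on load.
#'
#' @param path file path.
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect <- c(FEATURE_COLUMNS, "label")
  if (!identical(names(df), expect))
    stop("feature CSV schema error: columns must be exactly ",
         paste(expect, collapse = ", "), call. = FALSE)
  structure(df, class = c("feature_matrix", "data.frame"))
}

#' @rdname read_features_csv
#' @param x a `"feature_matrix"`.
#' @export
write_features_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated SVM with a median-heuristic Gaussian kernel
#'
#' Stratified k-fold cross-validation of a radial-basis SVM whose kernel
#' length scale is set by the median heuristic: on each fold's training rows
#' (standardized with training-fold statistics only), the kernel parameter
#' is `gamma = 1 / (2 * median(pairwise Euclidean distance)^2)`. Accuracy is
#' the average of the per-fold validation accuracies; the confusion matrix
#' pools the validation predictions of all folds.
#'
#' @param x a [build_features()] matrix (or any data frame whose last
#'   column, or a column named `label`, holds the class).
#' @param folds number of folds; every class needs at least `folds` rows.
#' @param seed integer seed driving the fold assignment.
#' @param cost SVM soft-margin cost.
#' @param roc logical; also compute one-vs-rest ROC curves (needs
#'   probability estimates, slower).
#' @return an object of class `"cifes_cv"`: `accuracy`, `fold_accuracy`,
#'   `confusion`, `roc` (named list of sensitivity/specificity frames or
#'   `NULL`), `folds`, `n`.
#' @export
crossval_svm <- function(x, folds = 10, seed = 1, cost = 1, roc = FALSE) {
  df <- as.data.frame(x)
  if (!"label" %in% names(df))
    stop("feature matrix must carry a 'label' column", call. = FALSE)
  labels <- as.character(df$label)
  feats <- as.matrix(df[setdiff(names(df), "label")])
  if (anyNA(feats)) stop("feature matrix has missing values", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2)
    stop("need at least 2 classes to cross-validate", call. = FALSE)
  if (any(tab < folds))
    stop(sprintf("every class needs at least %d rows (got: %s)", folds,
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")),
         call. = FALSE)
  set.seed(seed)
  fold_of <- stratified_folds(labels, folds)
  classes <- sort(unique(labels))
  pred_all <- character(nrow(feats))
  prob_all <- if (roc) matrix(NA_real_, nrow(feats), length(classes),
                              dimnames = list(NULL, classes))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    mu <- colMeans(feats[tr, , drop = FALSE])
    sg <- apply(feats[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    std <- sweep(sweep(feats, 2, mu), 2, sg, "/")
    med <- stats::median(stats::dist(std[tr, , drop = FALSE]))
    if (!is.finite(med) || med <= 0) med <- 1
    gamma <- 1 / (2 * med^2)
    fit <- e1071::svm(std[tr, , drop = FALSE], factor(labels[tr]),
                      kernel = "radial", gamma = gamma, cost = cost,
                      scale = FALSE, probability = roc)
    pr <- stats::predict(fit, std[!tr, , drop = FALSE], probability = roc)
    pred_all[!tr] <- as.character(pr)
    if (roc) {
      pm <- attr(pr, "probabilities")
      prob_all[!tr, colnames(pm)] <- pm
    }
    fold_acc[f] <- mean(as.character(pr) == labels[!tr])
  }
  confusion <- table(truth = factor(labels, classes),
                     predicted = factor(pred_all, classes))
  roc_list <- NULL
  if (roc) {
    roc_list <- lapply(classes, function(cl) {
      r <- pROC::roc(response = labels == cl, predictor = prob_all[, cl],
                     quiet = TRUE, direction = "<")
      data.frame(sensitivity = r$sensitivities,
                 specificity = r$specificities)
    })
    names(roc_list) <- classes
  }
  structure(list(accuracy = mean(fold_acc), fold_accuracy = fold_acc,
                 confusion = confusion, roc = roc_list,
                 folds = folds, n = nrow(feats), classes = classes,
                 seed = seed),
            class = "cifes_cv")
}

#' @export
print.cifes_cv <- function(x, ...) {
  cat(sprintf("<cifes_cv> %d-fold CV on %d rows, %d classes\n", x$folds,
              x$n, length(x$classes)))
  cat(sprintf("  accuracy %.3f (folds %.3f-%.3f)\n", x$accuracy,
              min(x$fold_accuracy), max(x$fold_accuracy)))
  print(x$confusion)
  invisible(x)
}

#' Day-over-day discriminability trend
#'
#' For each treatment session, runs a binary patient-vs-healthy
#' [crossval_svm()] of the session's cycles against the same healthy
#' reference rows and reports the accuracy sequence in session order. As a
#' patient's gait normalizes the two classes blend and the accuracy decays
#' toward chance — the rehabilitation signature.
#'
#' @param sessions list of `"feature_matrix"` frames, one per session, in
#'   temporal order.
#' @param reference `"feature_matrix"` of healthy rows shared by every
#'   comparison.
#' @param folds,seed,cost passed to [crossval_svm()].
#' @return numeric vector of per-session CV accuracies.
#' @export
rehab_trend <- function(sessions, reference, folds = 10, seed = 1,
                        cost = 1) {
  stopifnot(is.list(sessions), length(sessions) >= 1)
  ref <- as.data.frame(reference)
  ref$label <- "healthy"
  vapply(seq_along(sessions), function(i) {
    ses <- as.data.frame(sessions[[i]])
    ses$label <- "patient"
    both <- rbind(ses[c(FEATURE_COLUMNS, "label")],
                  ref[c(FEATURE_COLUMNS, "label")])
    crossval_svm(both, folds = folds, seed = seed + i - 1,
                 cost = cost)$accuracy
  }, numeric(1))
}
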