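# Splitting and evaluation: stratified train/test split (optionally grouped
# by subject so no subject spans splits), confusion-matrix metrics, and the
# F1 harmonic mean. The positive class for precision/recall/specificity is
# the disease class ("hcq") throughout.

#' Stratified train/test split
#'
#' Per class, `round(train_fraction * class size)` items go to training,
#' reproducibly under `seed`. With `group_ids`, whole groups (e.g. subjects)
#' are assigned to one side, keeping the class-wise training fraction as
#' close to the target as the group sizes allow.
#'
#' @param labels Vector of class labels, one per item.
#' @param train_fraction Fraction in (0, 1); a split leaving any class with
#'   an empty train or test side is an error.
#' @param seed Integer RNG seed.
#' @param group_ids Optional vector, same length as `labels`; items sharing
#'   a group id stay on one side.
#' @return A `split_spec`: list with integer index vectors `train` and
#'   `test`, and `counts` (per-class train/test/total).
#' @examples
#' sp <- stratified_split(rep(c("normal", "hcq"), c(66, 110)), 0.8, seed = 1)
#' sp$counts
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1,
                             group_ids = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1 (both splits non-empty)")
  }
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 members")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    if (is.null(group_ids)) {
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1), length(idx) - 1)
      train_idx <- c(train_idx, sample(idx, n_train))
    } else {
      gids <- unique(group_ids[idx])
      gids <- sample(gids)
      sizes <- vapply(gids, function(g) sum(group_ids[idx] == g), integer(1))
      target <- round(train_fraction * length(idx))
      take <- cumsum(sizes) <= target
      if (!any(take)) take[1] <- TRUE
      if (all(take)) take[length(take)] <- FALSE
      sel <- gids[take]
      train_idx <- c(train_idx, idx[group_ids[idx] %in% sel])
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  test_idx <- setdiff(seq_along(labels), train_idx)
  counts <- t(sapply(classes, function(cl) {
    c(train = sum(labels[train_idx] == cl),
      test = sum(labels[test_idx] == cl),
      total = sum(labels == cl))
  }))
  structure(list(train = sort(train_idx), test = sort(test_idx),
                 counts = counts, train_fraction = train_fraction,
                 seed = seed),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec>\n"); print(x$counts); invisible(x)
}

#' Classifier metrics from a 2x2 confusion matrix
#'
#' With the positive class P and negative class N:
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), F1 = harmonic mean of precision and recall.
#' A ratio with a zero denominator is reported as 0 and flagged in
#' `undefined`.
#'
#' @param cm 2x2 matrix of counts with rows = truth, cols = prediction, and
#'   dimnames naming the classes identically on both axes.
#' @param positive_class The disease / positive label (default `"hcq"`).
#' @param dataset_variant Optional tag (`"ORI"` or `"HSI"`) carried through.
#' @return A `metrics_report` list.
#' @examples
#' cm <- matrix(c(20, 2, 1, 12), 2, byrow = TRUE,
#'              dimnames = list(c("hcq", "normal"), c("hcq", "normal")))
#' metrics_from_confusion(cm)$accuracy # 32/35
#' @export
metrics_from_confusion <- function(cm, positive_class = "hcq",
                                   dataset_variant = NA) {
  cm <- as.matrix(cm)
  if (!identical(dim(cm), c(2L, 2L)) || sum(cm) == 0) {
    stop("cm must be a non-empty 2x2 confusion matrix")
  }
  if (is.null(dimnames(cm))) stop("cm needs dimnames naming the classes")
  pos <- positive_class
  neg <- setdiff(rownames(cm), pos)
  if (length(neg) != 1 || !pos %in% rownames(cm)) {
    stop("positive_class must be one of the two classes in cm")
  }
  tp <- cm[pos, pos]; fn <- cm[pos, neg]
  fp <- cm[neg, pos]; tn <- cm[neg, neg]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  undefined <- c(precision = is.na(precision), recall = is.na(recall),
                 specificity = is.na(specificity))
  precision <- if (is.na(precision)) 0 else precision
  recall <- if (is.na(recall)) 0 else recall
  specificity <- if (is.na(specificity)) 0 else specificity
  structure(
    list(confusion = cm, accuracy = (tp + tn) / sum(cm),
         precision = precision, recall = recall, specificity = specificity,
         f1 = f1_from_pr(precision, recall),
         positive_class = pos, dataset_variant = dataset_variant,
         undefined = undefined),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report>%s acc = %.3f, prec = %.3f, rec = %.3f, spec = %.3f, f1 = %.3f\n",
    if (is.na(x$dataset_variant)) "" else paste0(" [", x$dataset_variant, "]"),
    x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  invisible(x)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in `[0, 1]`. Both zero returns 0 with a
#'   `degenerate` attribute flag.
#' @return The F1 score.
#' @examples
#' round(f1_from_pr(0.82, 0.75), 2) # 0.78
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    return(structure(0, degenerate = TRUE))
  }
  2 * precision * recall / (precision + recall)
}

#' Evaluate a classifier on labelled data
#'
#' @param model A trained `cnn_classifier`.
#' @param data Manifest data frame (`file`, `label`) or list with `x`, `y`.
#' @param positive_class,dataset_variant Passed to
#'   [metrics_from_confusion()].
#' @return A `metrics_report`.
#' @export
evaluate_classifier <- function(model, data, positive_class = "hcq",
                                dataset_variant = NA) {
  truth <- as.character(if (is.data.frame(data)) data$label else data$y)
  pred <- as.character(predict(model, data))
  lv <- model$classes
  cm <- table(factor(truth, lv), factor(pred, lv))
  metrics_from_confusion(unclass(as.matrix(cm)), positive_class,
                         dataset_variant)
}
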