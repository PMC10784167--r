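#' Confusion matrix from label vectors
#'
#' Counts samples into a true-class-by-predicted-class table. Labels are
#' integers in `1..n_classes` (factors are converted by level index).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param n_classes Number of classes; defaults to the maximum label seen.
#' @return Integer `n_classes x n_classes` matrix of class
#'   `confusion_matrix`, rows = true class, columns = predicted class.
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = NULL) {
  if (is.factor(y_true)) y_true <- as.integer(y_true)
  if (is.factor(y_pred)) y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  n_classes <- as.integer(n_classes %||% max(y_true, y_pred, 1L))
  if (length(y_true) > 0 &&
      (any(y_true < 1L) || any(y_true > n_classes) ||
       any(y_pred < 1L) || any(y_pred > n_classes))) {
    stop("labels must lie in 1..n_classes", call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               pred = seq_len(n_classes)))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

# one-vs-rest cell counts for class k
ovr_counts <- function(cm, k) {
  total <- sum(cm)
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  list(tp = tp, fp = fp, fn = fn, tn = total - tp - fp - fn)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning 0", what))
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the diagonal fraction. Per class, one-vs-rest
#' reductions give TP/FP/FN/TN and from them precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, F1 `2PS/(P+S)` and the binary accuracy
#' `(TP+TN)/total`; macro values average over classes. In the two-class case
#' the per-class row of the positive class is exactly the binary formula
#' set. An undefined ratio (zero denominator) is reported as 0 with a
#' warning.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix).
#' @param positive Positive class index used for the headline binary metrics
#'   when `n_classes == 2` (default 1).
#' @return An object of class `metrics_report`: `accuracy`, `precision`,
#'   `sensitivity`, `f1` (binary or macro, per the class count), `macro_*`
#'   fields, and `per_class` (a tibble).
#' @examples
#' cm <- confusion_matrix(c(1, 1, 1, 2), c(1, 1, 2, 2), 2)
#' classification_metrics(cm)$accuracy
#' @export
classification_metrics <- function(cm, positive = 1L) {
  cm <- unclass(as.matrix(cm))
  if (sum(cm) < 1) stop("confusion matrix must contain at least one sample", call. = FALSE)
  C <- nrow(cm)
  rows <- lapply(seq_len(C), function(k) {
    ct <- ovr_counts(cm, k)
    prec <- safe_div(ct$tp, ct$tp + ct$fp, sprintf("precision for class %d", k))
    sens <- safe_div(ct$tp, ct$tp + ct$fn, sprintf("sensitivity for class %d", k))
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    tibble::tibble(
      class = k, tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
      precision = prec, sensitivity = sens, f1 = f1,
      accuracy = (ct$tp + ct$tn) / sum(cm)
    )
  })
  per_class <- do.call(rbind, rows)
  overall_acc <- sum(diag(cm)) / sum(cm)
  macro <- c(
    precision = mean(per_class$precision),
    sensitivity = mean(per_class$sensitivity),
    f1 = mean(per_class$f1)
  )
  if (C == 2L) {
    head_row <- per_class[per_class$class == positive, ]
    headline <- c(precision = head_row$precision,
                  sensitivity = head_row$sensitivity, f1 = head_row$f1)
  } else {
    headline <- macro
  }
  structure(
    list(
      accuracy = overall_acc,
      precision = unname(headline["precision"]),
      sensitivity = unname(headline["sensitivity"]),
      f1 = unname(headline["f1"]),
      macro_precision = unname(macro["precision"]),
      macro_sensitivity = unname(macro["sensitivity"]),
      macro_f1 = unname(macro["f1"]),
      per_class = per_class,
      n_classes = C
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d classes\n", x$n_classes))
  cat(sprintf("  accuracy %.4f | precision %.4f | sensitivity %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$sensitivity, x$f1))
  invisible(x)
}

#' Convolution cost of standard vs depthwise-separable filtering
#'
#' A standard convolution over an `hi x wi` feature map with `di` input and
#' `dj` output channels and a `k x k` kernel costs `hi*wi*di*dj*k^2`
#' multiply-accumulates; the depthwise-separable factorization (per-channel
#' spatial filtering plus 1x1 pointwise mixing) costs
#' `hi*wi*di*(dj + k^2)`. Their ratio `dj*k^2 / (dj + k^2)` — the speedup —
#' is independent of the spatial size and input depth.
#'
#' @param hi,wi Feature-map height and width.
#' @param di,dj Input and output channel counts.
#' @param k Kernel side length.
#' @return A list with `c_nor`, `c_sep` and `ratio`.
#' @examples
#' conv_costs(1, 1, 1, 64, 3)$ratio  # 576 / 73
#' @export
conv_costs <- function(hi, wi, di, dj, k) {
  args <- c(hi = hi, wi = wi, di = di, dj = dj, k = k)
  if (any(args <= 0) || any(args != as.integer(args))) {
    stop("all arguments must be positive integers", call. = FALSE)
  }
  c_nor <- hi * wi * di * dj * k^2
  c_sep <- hi * wi * di * (dj + k^2)
  list(c_nor = c_nor, c_sep = c_sep, ratio = dj * k^2 / (dj + k^2))
}
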