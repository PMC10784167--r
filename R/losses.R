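#' @title Class-imbalance loss family
#' @description Cross entropy and its weighted and focal variants, plus the
#'   error-rate-driven class-weight scheduler. Probabilities are rows of a
#'   samples-by-classes matrix summing to 1; targets are one-hot rows or
#'   integer class labels. The true-class probability is floored at `1e-12`
#'   before the logarithm so a zero probability never yields `-Inf`.
#' @name losses
NULL

PROB_FLOOR <- 1e-12

# normalize (probs, targets) inputs to matrices; returns list(P, Z)
as_prob_target <- function(probs, targets) {
  P <- as.matrix(probs)
  if (any(P < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("each probability row must sum to 1 (within 1e-9)", call. = FALSE)
  }
  C <- ncol(P)
  if (is.matrix(targets)) {
    Z <- targets
    if (!all(rowSums(Z) == 1) || !all(Z %in% c(0, 1))) {
      stop("target rows must be one-hot", call. = FALSE)
    }
  } else {
    lab <- as.integer(targets)
    if (any(lab < 1L) || any(lab > C)) {
      stop("labels must lie in 1..n_classes", call. = FALSE)
    }
    Z <- matrix(0, length(lab), C)
    Z[cbind(seq_along(lab), lab)] <- 1
  }
  if (nrow(Z) != nrow(P)) {
    stop("`probs` and `targets` must have the same number of samples", call. = FALSE)
  }
  list(P = P, Z = Z)
}

floored_true_prob <- function(P, Z) {
  p_true <- rowSums(P * Z)
  if (any(p_true < PROB_FLOOR)) {
    warning("true-class probability below 1e-12 floored before log")
    p_true <- pmax(p_true, PROB_FLOOR)
  }
  p_true
}

#' Cross-entropy loss
#'
#' `-sum_i z_i . ln P(y_i)` over samples — the sum convention; set
#' `reduce = "mean"` for the per-sample average.
#'
#' @param probs Samples-by-classes probability matrix (rows sum to 1).
#' @param targets One-hot matrix of the same shape, or integer labels in
#'   `1..n_classes`.
#' @param reduce `"sum"` (default) or `"mean"`.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(matrix(0.25, 1, 4), 1L)  # log(4)
#' @export
cross_entropy <- function(probs, targets, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  pt <- as_prob_target(probs, targets)
  loss <- -log(floored_true_prob(pt$P, pt$Z))
  if (reduce == "mean") mean(loss) else sum(loss)
}

#' Weighted cross-entropy loss
#'
#' `-sum_i z_i . [w * ln P(y_i)]` with a per-class weight vector `w`; each
#' sample's log-probability is weighted by its true class's weight. With
#' all-ones weights this equals [cross_entropy()] exactly.
#'
#' @inheritParams cross_entropy
#' @param w Non-negative per-class weight vector of length `n_classes`.
#' @return Scalar loss.
#' @examples
#' weighted_cross_entropy(matrix(c(0.7, 0.3), 1), 1L, w = c(2, 1))
#' @export
weighted_cross_entropy <- function(probs, targets, w, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  pt <- as_prob_target(probs, targets)
  if (length(w) != ncol(pt$P)) {
    stop("`w` must have one weight per class", call. = FALSE)
  }
  if (any(w < 0)) stop("class weights must be non-negative", call. = FALSE)
  w_true <- as.numeric(pt$Z %*% w)
  loss <- -w_true * log(floored_true_prob(pt$P, pt$Z))
  if (reduce == "mean") mean(loss) else sum(loss)
}

#' Focal loss
#'
#' Cross entropy with each sample's contribution decayed by
#' `(1 - P(y_i))^delta`, down-weighting well-classified samples. `delta = 0`
#' reduces exactly to [cross_entropy()].
#'
#' @inheritParams cross_entropy
#' @param delta Non-negative focusing exponent (default 2).
#' @return Scalar loss, never exceeding the cross entropy.
#' @examples
#' focal_loss(matrix(c(0.5, 0.5), 1), 1L, delta = 2)  # 0.25 * log(2)
#' @export
focal_loss <- function(probs, targets, delta = 2, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (delta < 0) stop("`delta` must be non-negative", call. = FALSE)
  pt <- as_prob_target(probs, targets)
  p_true <- floored_true_prob(pt$P, pt$Z)
  loss <- -(1 - p_true)^delta * log(p_true)
  if (reduce == "mean") mean(loss) else sum(loss)
}

#' Per-class error rates from a confusion matrix
#'
#' `Er_i = 1 - TPR_i` with `TPR_i` the diagonal count over the true-class row
#' total. A class with no true samples gets error rate 0 with a warning.
#'
#' @param cm Confusion matrix (true class x predicted class), as from
#'   [confusion_matrix()].
#' @return Numeric vector of per-class error rates in `[0, 1]`.
#' @examples
#' class_error_rates(rbind(c(3, 1), c(0, 4)))
#' @export
class_error_rates <- function(cm) {
  cm <- as.matrix(cm)
  totals <- rowSums(cm)
  tpr <- rep(0, nrow(cm))
  if (any(totals == 0)) {
    warning("class(es) with no true samples: error rate defined as 0")
    tpr[totals == 0] <- 1
  }
  ok <- totals > 0
  tpr[ok] <- diag(cm)[ok] / totals[ok]
  1 - tpr
}

#' Monotone transforms for the class-weight scheduler
#'
#' Returns the transform `rho` applied to class error rates before
#' normalization: identity, cube, or the exponential family `exp(s * y)`
#' with slope 1, 10 or 100. Steeper transforms put ever more weight on the
#' worst-classified class.
#'
#' @param kind One of `"identity"`, `"cube"`, `"exp1"`, `"exp10"`, `"exp100"`.
#' @return A vectorized function on `[0, 1]`.
#' @export
rho_transform <- function(kind = c("identity", "cube", "exp1", "exp10", "exp100")) {
  kind <- match.arg(kind)
  switch(kind,
    identity = function(y) y,
    cube = function(y) y^3,
    exp1 = function(y) exp(y),
    exp10 = function(y) exp(10 * y),
    exp100 = function(y) exp(100 * y)
  )
}

#' Error-rate-driven class weights
#'
#' `w_i = rho(Er_i) / sum_j rho(Er_j)`: classes with higher error rates get
#' proportionally more weight in the next training repetition. If the
#' denominator is zero (all error rates zero under identity or cube rho),
#' uniform weights are returned with a warning.
#'
#' @param er Per-class error rates in `[0, 1]`.
#' @param rho A transform name accepted by [rho_transform()], or a function.
#' @return Normalized weight vector summing to 1.
#' @examples
#' update_class_weights(c(0.1, 0.3), "identity")  # c(0.25, 0.75)
#' @export
update_class_weights <- function(er, rho = "identity") {
  if (any(er < 0) || any(er > 1)) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  f <- if (is.function(rho)) rho else rho_transform(rho)
  v <- f(er)
  s <- sum(v)
  if (s == 0) {
    warning("all transformed error rates are zero; returning uniform weights")
    return(rep(1 / length(er), length(er)))
  }
  v / s
}
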