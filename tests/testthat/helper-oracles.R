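# Independent oracles used to cross-check package computations.

# plain global histogram equalization straight from the cumulative histogram
global_hist_eq_oracle <- function(img, L = 256L) {
  H <- tabulate(as.integer(img) + 1L, nbins = L)
  C <- cumsum(H)
  matrix((L - 1) * C[as.integer(img) + 1L] / length(img), nrow(img), ncol(img))
}

# binary one-vs-rest metrics computed directly from the formula set,
# independently of classification_metrics()
metrics_oracle_class <- function(cm, k) {
  tp <- cm[k, k]
  fp <- sum(cm[, k]) - tp
  fn <- sum(cm[k, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(accuracy = (tp + tn) / sum(cm), precision = prec,
    sensitivity = sens, f1 = f1)
}

# Hill estimator of the tail index from the k largest order statistics
hill_estimator <- function(x, k = 1000L) {
  x <- sort(x, decreasing = TRUE)
  k / sum(log(x[seq_len(k)] / x[k + 1L]))
}

sample_kurtosis <- function(x) {
  z <- x - mean(x)
  length(x) * sum(z^4) / sum(z^2)^2
}

# small deterministic synthetic dataset shared across tests
toy_dataset <- function(n = 30L, size = 48L, seed = 7L, classes = 1:3) {
  spec <- synthetic_spec(n_per_class = rep(n, 3), image_size = size, seed = seed)
  ds <- generate_dataset(spec)
  Filter(function(r) r$label %in% classes, ds)
}
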