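# Independent brute-force oracles. These recompute quantities from their
# definitions by direct enumeration and must stay independent of the
# package's implementation paths.

oracle_entropy_16bin <- function(drr) {
  x <- pmin(pmax(drr, -0.5), 0.5)
  b <- seq(-0.5, 0.5, length.out = 17)
  h <- 0
  for (i in 1:16) {
    cnt <- if (i < 16) sum(x >= b[i] & x < b[i + 1])
           else sum(x >= b[16] & x <= b[17])
    if (cnt > 0) {
      p <- cnt / length(x)
      h <- h - p * log(p)
    }
  }
  h
}

oracle_ks_two_sample <- function(x, y) {
  pts <- sort(c(x, y))
  d <- 0
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

oracle_mean_pairwise_cor <- function(mat) {
  n <- ncol(mat)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, stats::cor(mat[, i], mat[, j]))
  mean(vals)
}

oracle_confusion <- function(true, pred, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(true))
    m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  m
}

oracle_f1 <- function(cm, class) {
  i <- match(class, rownames(cm))
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  den <- 2 * tp + fp + fn
  if (den == 0) 1 else 2 * tp / den
}

# Triple-sum form of the K-class MCC (independent of the covariance form
# used in the package).
oracle_multiclass_mcc <- function(cm) {
  k <- nrow(cm)
  num <- 0
  for (a in 1:k) for (l in 1:k) for (m in 1:k)
    num <- num + cm[a, a] * cm[l, m] - cm[a, l] * cm[m, a]
  d1 <- 0; d2 <- 0
  for (a in 1:k) {
    pa <- sum(cm[a, ])
    qa <- sum(cm[, a])
    d1 <- d1 + pa * (sum(cm) - pa)
    d2 <- d2 + qa * (sum(cm) - qa)
  }
  den <- sqrt(d1) * sqrt(d2)
  if (den == 0) 0 else num / den
}
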