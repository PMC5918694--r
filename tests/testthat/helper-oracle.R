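# Independent oracles the implementation is checked against.

# AUROC by exhaustive positive-negative pair concordance (ties count 1/2).
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Average precision by direct summation over positives in rank order.
ap_oracle <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  hits <- 0; s <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) { hits <- hits + 1; s <- s + hits / i }
  }
  s / sum(y)
}

# Deterministic full-batch proximal gradient (FISTA) on the same penalized
# logistic objective; independent of the SGD path.
prox_gradient_enet <- function(X, y, alpha, l1_ratio, iters = 4000) {
  n <- nrow(X); p <- ncol(X)
  lam1 <- alpha * l1_ratio; lam2 <- alpha * (1 - l1_ratio)
  L <- (svd(X)$d[1]^2) / (4 * n) + lam2 + 0.25 / n
  w <- rep(0, p); b <- 0; wv <- w; bv <- b; tk <- 1
  for (it in seq_len(iters)) {
    m <- drop(X %*% wv) + bv
    pr <- 1 / (1 + exp(-m))
    gw <- drop(crossprod(X, pr - y)) / n + lam2 * wv
    gb <- mean(pr - y)
    wn <- wv - gw / L; bn <- bv - gb / L
    wn <- sign(wn) * pmax(abs(wn) - lam1 / L, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    wv <- wn + (tk - 1) / tn * (wn - w)
    bv <- bn + (tk - 1) / tn * (bn - b)
    w <- wn; b <- bn; tk <- tn
  }
  list(weights = w, intercept = b)
}
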