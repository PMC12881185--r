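# Independent oracles kept deliberately naive: they re-derive the same
# quantities by brute force and must never share code with the package.

# ssGSEA by an explicit walk over positions, summing the running ECDF
# difference step by step.
naiveSsgsea <- function(ranks, setIdx, wExp = 0.25) {
  N <- length(ranks)
  ord <- order(ranks, decreasing = TRUE)   # walk: highest rank first
  inSet <- ord %in% setIdx
  W <- sum(ranks[setIdx]^wExp)
  es <- 0
  pin <- 0
  pout <- 0
  for (i in seq_len(N)) {
    g <- ord[i]
    if (inSet[i]) pin <- pin + ranks[g]^wExp / W
    else pout <- pout + 1 / (N - length(setIdx))
    es <- es + (pin - pout)
  }
  es
}

# AUC by exhaustive pairwise comparison (ties half credit).
pairwiseAuc <- function(score, labels) {
  xs <- score[labels == "R"]
  ys <- score[labels == "NR"]
  tot <- 0
  for (a in xs) for (b in ys)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

# Youden threshold by brute force over a dense candidate sweep.
bruteYouden <- function(probs, labels) {
  pos <- labels == "R"
  u <- sort(unique(probs))
  cand <- c(u[1] / 2, (u[-1] + u[-length(u)]) / 2, (u[length(u)] + 1) / 2)
  best <- -Inf; bestTh <- NA
  for (th in cand) {
    calls <- probs >= th
    j <- sum(calls & pos) / sum(pos) + sum(!calls & !pos) / sum(!pos) - 1
    if (j > best + 1e-12) { best <- j; bestTh <- th }
  }
  bestTh
}

# Lasso-penalized logistic regression (alpha = 1) with a constant offset,
# solved by IRLS + cyclic coordinate descent with soft-thresholding.
# Objective: (1/n) sum[-y eta + log(1+e^eta)] + lambda * ||beta||_1,
# eta = b0 + offset + X beta; intercept unpenalized; no standardization.
cdLassoLogistic <- function(x, y, lambda, offset = 0,
                            maxOuter = 200, maxInner = 500, tol = 1e-11) {
  n <- nrow(x); p <- ncol(x)
  b0 <- 0; b <- rep(0, p)
  offs <- rep_len(offset, n)
  for (outer in seq_len(maxOuter)) {
    bPrev <- c(b0, b)
    eta <- b0 + offs + drop(x %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta - offs + (y - mu) / w
    for (inner in seq_len(maxInner)) {
      bIn <- c(b0, b)
      r <- z - b0 - drop(x %*% b)
      b0new <- b0 + sum(w * r) / sum(w)
      r <- r - (b0new - b0); b0 <- b0new
      for (j in seq_len(p)) {
        rj <- r + x[, j] * b[j]
        sj <- sum(w * x[, j] * rj) / n
        denom <- sum(w * x[, j]^2) / n
        bj <- sign(sj) * max(abs(sj) - lambda, 0) / denom
        r <- rj - x[, j] * bj
        b[j] <- bj
      }
      if (max(abs(c(b0, b) - bIn)) < tol) break
    }
    if (max(abs(c(b0, b) - bPrev)) < 1e-10) break
  }
  list(intercept = b0, beta = b)
}

# Log-rank O-E/V tally over distinct event times (hypergeometric variance).
manualLogrank <- function(times, events, groups) {
  g1 <- sort(unique(groups))[1]
  evTimes <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in evTimes) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & groups == g1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
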