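# Brute-force metric oracles, written as plain loops so they share no code
# with the implementation they check.

oracle_from_confusion <- function(cm) {
  K <- nrow(cm); n <- sum(cm)
  tp <- diag(cm)
  prec <- rec <- f1 <- numeric(K)
  for (k in 1:K) {
    predk <- sum(cm[, k]); truek <- sum(cm[k, ])
    prec[k] <- if (predk == 0) 0 else cm[k, k] / predk
    rec[k] <- if (truek == 0) 0 else cm[k, k] / truek
    f1[k] <- if (prec[k] + rec[k] == 0) 0 else
      2 * prec[k] * rec[k] / (prec[k] + rec[k])
  }
  s <- n; c0 <- sum(tp)
  num <- c0 * s - sum(colSums(cm) * rowSums(cm))
  den <- sqrt(s^2 - sum(colSums(cm)^2)) * sqrt(s^2 - sum(rowSums(cm)^2))
  list(accuracy = sum(tp) / n, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), mcc = if (den == 0) 0 else num / den)
}

auc_pairwise <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# reconstruct (y_true, y_prob) that yield exactly a target confusion matrix
data_for_confusion <- function(cm) {
  K <- nrow(cm); lev <- letters[1:K]
  yt <- character(); prob <- NULL
  for (i in 1:K) for (j in 1:K) {
    m <- cm[i, j]
    if (m == 0) next
    yt <- c(yt, rep(lev[i], m))
    row <- rep((1 - 0.9) / (K - 1), K); row[j] <- 0.9
    if (K == 2) row <- if (j == 2) c(0.1, 0.9) else c(0.9, 0.1)
    prob <- rbind(prob, matrix(row, m, K, byrow = TRUE))
  }
  list(y = factor(yt, lev), prob = prob)
}
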