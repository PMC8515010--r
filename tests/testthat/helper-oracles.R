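## Independent brute-force oracles used across the suite. These re-derive
## each quantity from first principles (loops, enumeration) and must stay
## independent of the package implementations they check.

## univariate Fisher discriminant pipeline: sort by z (ties by sample ID),
## take tails of size max(2, floor(f*n)), score on log10(1+TPM)
oracleFisher <- function(tpmMat, z, f = 0.15) {
  samples <- colnames(tpmMat)
  ord <- samples[order(z[samples], samples)]
  nt <- max(2, floor(f * length(samples)))
  low <- ord[1:nt]
  high <- rev(ord)[1:nt]
  apply(tpmMat, 1, function(row) {
    a <- log10(1 + row[low]); b <- log10(1 + row[high])
    num <- abs(mean(b) - mean(a))
    den <- sqrt(var(a) + var(b))
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  })
}

## exact two-sided Mann-Whitney p by full enumeration of rank splits
oracleMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  uStat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u0 <- uStat(seq_len(n1))
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, uStat)
  mid <- n1 * n2 / 2
  mean(abs(us - mid) >= abs(u0 - mid) - 1e-9)
}

## all-pairs AUC
oracleAuc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

## naive KNN with index-order tie-break, on an already-standardized space
oracleKnn <- function(trainX, trainY, queryX, k) {
  apply(queryX, 1, function(q) {
    d <- apply(trainX, 1, function(t) sqrt(sum((t - q)^2)))
    mean(trainY[order(d, seq_along(d))[1:k]])
  })
}

## stratified fold dealer replicated independently (same algorithm spec:
## per class, shuffle then deal round-robin) for CV cross-checks
oracleFolds <- function(labels, nFolds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}
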