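# Independent brute-force oracles, kept deliberately naive so they cannot
# share a bug with the implementation they check.

# AUC by explicit pair counting: wins + half-ties over all pos x neg pairs
brute_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Youden scan: enumerate every midpoint candidate (plus sentinels), compute
# sens/spec by direct counting, take max J with smallest-cutoff tie-break
brute_youden <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cand <- c(-Inf, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2, Inf)
  sens <- sapply(cand, function(t) mean(pos > t))
  spec <- sapply(cand, function(t) mean(neg <= t))
  j <- sens + spec - 1
  i <- which(j > max(j) - 1e-12)[1]   # cand is sorted increasing
  list(cutoff = cand[i], youden_j = j[i], sensitivity = sens[i],
       specificity = spec[i])
}

# small random two-group cohort, heavy ties when tie_prone
random_cohort <- function(tie_prone = TRUE) {
  n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
  if (tie_prone) {
    pos <- sample(1:6, n1, replace = TRUE) + sample(c(0, 0.5), n1, replace = TRUE)
    neg <- sample(1:6, n2, replace = TRUE)
  } else {
    pos <- rnorm(n1, 1); neg <- rnorm(n2)
  }
  list(pos = pos, neg = neg,
       values = c(pos, neg),
       labels = rep(c("suboptimal", "optimal"), c(n1, n2)))
}

sub_opt_labels <- function(n1, n2) rep(c("suboptimal", "optimal"), c(n1, n2))
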