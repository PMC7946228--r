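# Independent oracles used across the suite. These re-derive expected
# values by enumeration / direct formula evaluation and never call the
# implementation paths they check.

# exact minimal L1 cost of fitting a non-increasing, [0,1]-bounded
# sequence to each row of X, by dynamic programming over a value grid.
# For inputs whose values lie on the grid this equals the continuous
# optimum (L1 isotonic solutions can always be taken on the input values).
l1_antitonic_min_cost <- function(X, grid = seq(0, 1, by = 0.1)) {
  X <- as.matrix(X)
  k <- ncol(X)
  # reverse columns: non-increasing becomes non-decreasing in grid index
  Xr <- X[, k:1, drop = FALSE]
  m <- length(grid)
  M <- abs(outer(Xr[, 1], grid, "-"))
  for (i in 2:k) {
    for (j in 2:m) M[, j] <- pmin(M[, j], M[, j - 1])  # prefix min over levels
    M <- M + abs(outer(Xr[, i], grid, "-"))
  }
  apply(M, 1, min)
}

# naive running-sum enrichment score (classic weighted KS statistic)
es_brute <- function(scores, set, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  nm <- names(scores)[ord]
  s <- abs(scores[ord])^weight
  hit <- nm %in% set
  k <- sum(hit)
  n <- length(s)
  nr <- sum(s[hit])
  inc <- ifelse(hit, if (nr > 0) s / nr else 1 / k, 0) -
    ifelse(hit, 0, 1 / (n - k))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# exact two-sided permutation p-value for a Spearman correlation
spearman_perm_p <- function(x, y) {
  n <- length(x)
  obs <- abs(cor(x, y, method = "spearman"))
  perms <- gtools_permutations(n)
  stats <- apply(perms, 1, function(p)
    abs(cor(x, y[p], method = "spearman")))
  mean(stats >= obs - 1e-12)
}

# all permutations of 1..n (small n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[j, ]])
      r <- r + 1L
    }
  }
  out
}

# trapezoidal AUC of a screen truth's expected viabilities over log10 dose
true_auc <- function(truth, concentrations = 10^(0:4)) {
  v <- true_viability(truth, concentrations)
  lx <- log10(concentrations)
  sum(diff(lx) * (head(v, -1) + tail(v, -1)) / 2)
}

# a small standard confluence fixture: one cell line / compound with a
# planted reducing threshold (first multiplier < 1) and arrest threshold
# (first multiplier == 0)
make_growth_fixture <- function(multipliers = c(1, 1, 0.5, 0, 0),
                                doses = 10^(0:4), reversible = FALSE,
                                baseline_rate = 0.035) {
  growth_truth("LX", "CX", baseline_rate = baseline_rate,
               drug_effect = stats::setNames(multipliers, doses),
               reversible = reversible)
}

planted_reducing <- function(multipliers, doses = 10^(0:4)) {
  i <- which(multipliers < 1)[1]
  if (is.na(i)) NA_real_ else doses[i]
}

planted_arrest <- function(multipliers, doses = 10^(0:4)) {
  i <- which(multipliers == 0)[1]
  if (is.na(i)) NA_real_ else doses[i]
}
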