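# Independent statistical oracles, kept deliberately separate from the
# package implementation they cross-check.

# Closed-form chi-square survival function for even df:
# Q(x, 2k) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
sf_even_df_series <- function(x, df) {
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Brute-force independence statistic: explicit double loop over cells with
# expected = row_total * col_total / grand_total.
brute_force_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Reference step-up BH: sort descending, running minimum of (m/rank)*p.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}
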