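## Independent brute-force oracles, kept free of the package's code paths.

## BH step-up from the definition: q_i = min over k >= rank(i) of
## p_(k) * n / k
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n))
    q[o[i]] <- min(vapply(i:n, function(k) p[o[k]] * n / k, 0))
  q
}

## two-sided Fisher p by summing hypergeometric point probabilities not
## exceeding the observed table's, over all tables with fixed margins
bruteFisher <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]; n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  support <- max(0, k - n):min(k, m)
  logp <- function(a) lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k)
  lp <- vapply(support, logp, 0)
  obs <- logp(tab[1, 1])
  sum(exp(lp[lp <= obs + 1e-7]))
}
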