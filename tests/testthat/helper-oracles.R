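# Independent brute-force template-counting oracles for the entropy
# statistics: plain nested loops straight from the definitions, sharing no
# code with the package's vectorized implementations.

oracle_cheb <- function(x, i, j, m) {
  d <- 0
  for (k in 0:(m - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
  d
}

oracle_apen <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    s <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) if (oracle_cheb(x, i, j, mm) <= r) cnt <- cnt + 1
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r_frac) {
  n <- length(x)
  r <- r_frac * sd(x)
  count <- function(mm) {
    nt <- n - m          # both lengths use the first n - m templates
    cnt <- 0
    for (i in 1:(nt - 1))
      for (j in (i + 1):nt)
        if (oracle_cheb(x, i, j, mm) <= r) cnt <- cnt + 1
    cnt
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0) return(log(B))   # same upper-bound sentinel as the package
  -log(A / B)
}

oracle_fuzzen <- function(x, m, r_frac, n_exp = 2) {
  n <- length(x)
  r <- max(r_frac * sd(x), .Machine$double.eps)
  phi <- function(mm) {
    nt <- n - m
    tpl <- vector("list", nt)
    for (i in 1:nt) {
      v <- x[i:(i + mm - 1)]
      tpl[[i]] <- v - mean(v)
    }
    s <- 0
    for (i in 1:nt)
      for (j in 1:nt)
        if (i != j) {
          d <- max(abs(tpl[[i]] - tpl[[j]]))
          s <- s + exp(-(d / r)^n_exp)
        }
    s / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}
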