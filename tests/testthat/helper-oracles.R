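# Independent brute-force oracles used to validate the package
# implementations. These deliberately follow the definitions literally
# (loops, exhaustive enumeration) and share no code with R/.

# mean pairwise Hamming distance over all unordered haplotype pairs
oracle_pi <- function(states) {
  n <- nrow(states)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    tot <- tot + sum(states[i, ] != states[j, ])
    np <- np + 1L
  }
  tot / np
}

# Tajima's D from the series definitions of the constants
oracle_tajd <- function(states) {
  n <- nrow(states)
  k <- colSums(states)
  S <- sum(k > 0 & k < n)
  if (S == 0) return(NaN)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  seg <- states[, k > 0 & k < n, drop = FALSE]
  (oracle_pi(seg) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site Weir-Cockerham (1984) components for haploid samples, scalar loop
oracle_fst_weighted <- function(states, labels) {
  pops <- sort(unique(labels))
  r <- length(pops)
  num <- 0; den <- 0
  for (s in seq_len(ncol(states))) {
    ni <- numeric(r); pi_ <- numeric(r)
    for (q in seq_len(r)) {
      rows <- which(labels == pops[q])
      ni[q] <- length(rows)
      pi_[q] <- mean(states[rows, s])
    }
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi_) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- 0
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NaN else num / den
}

# exhaustive nSL at one focal site: walk tracts pair by pair
oracle_nsl_site <- function(states, focal, cap = 100L) {
  n <- nrow(states); S <- ncol(states)
  tract <- function(i, j) {
    if (states[i, focal] != states[j, focal]) return(NA_real_)
    len <- 1L
    s <- focal - 1L
    while (s >= 1L && focal - s <= cap && states[i, s] == states[j, s]) {
      len <- len + 1L; s <- s - 1L
    }
    s <- focal + 1L
    while (s <= S && s - focal <= cap && states[i, s] == states[j, s]) {
      len <- len + 1L; s <- s + 1L
    }
    len
  }
  der <- which(states[, focal] == 1L)
  anc <- which(states[, focal] == 0L)
  if (length(der) < 2L || length(anc) < 2L) return(NULL)
  sl <- function(rows) {
    v <- c()
    for (i in seq_along(rows)[-length(rows)])
      for (j in (i + 1L):length(rows))
        v <- c(v, tract(rows[i], rows[j]))
    mean(v)
  }
  SL_D <- sl(der); SL_A <- sl(anc)
  list(SL_A = SL_A, SL_D = SL_D, nsl = log(SL_A / SL_D))
}

oracle_h12 <- function(states) {
  n <- nrow(states)
  keys <- character(n)
  for (i in seq_len(n)) keys[i] <- paste(states[i, ], collapse = ",")
  p <- sort(as.numeric(table(keys)) / n, decreasing = TRUE)
  H1 <- sum(p^2)
  p2 <- if (length(p) > 1) p[2] else 0
  c(H1 = H1, H12 = H1 + 2 * p[1] * p2)
}

# exact two-sided MWU by literal enumeration of all choose(n1+n2, n1) splits
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ustat <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  U <- ustat(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  mid <- n1 * n2 / 2
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    u <- ustat(pooled[idx[, j]], pooled[-idx[, j]])
    if (abs(u - mid) >= abs(U - mid) - 1e-9) hits <- hits + 1
  }
  list(U = U, p_value = hits / ncol(idx))
}

# random haplotype fixture; guarantees every site segregating
rand_hapmat <- function(n, S, pops = NULL) {
  repeat {
    m <- matrix(rbinom(n * S, 1L, runif(1, 0.2, 0.8)), nrow = n)
    k <- colSums(m)
    if (all(k > 0 & k < n)) break
  }
  haplotype_matrix(m, sort(sample.int(10000L, S)),
                   pop_labels = if (is.null(pops)) rep("POP1", n) else pops)
}
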