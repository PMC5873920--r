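#' Pairwise nucleotide diversity
#'
#' Mean number of differences between all unordered pairs of haplotypes across
#' the retained sites. Per site at derived-allele count `k` out of `n`
#' haplotypes, the contribution is `k (n - k) / choose(n, 2)`, so the total is
#' equivalent to the unbiased heterozygosity sum `sum_sites 2 p (1-p) n/(n-1)`.
#'
#' @param h a [haplotype_matrix()]
#' @param length_bp region length in bp for the per-site value; defaults to
#'   the positional span of the matrix
#' @return list with `pi_total` (mean pairwise differences, per haplotype
#'   pair) and `pi_per_site` (`pi_total / length_bp`)
#' @export
nucleotide_diversity <- function(h, length_bp = NULL) {
  n <- n_haplotypes(h)
  if (n < 2L) {
    warning("nucleotide diversity undefined for fewer than 2 haplotypes")
    return(list(pi_total = NaN, pi_per_site = NaN))
  }
  if (is.null(length_bp))
    length_bp <- if (ncol(h$states)) diff(range(h$positions)) + 1L else NA_real_
  if (ncol(h$states) == 0L)
    return(list(pi_total = 0, pi_per_site = if (is.na(length_bp)) NaN else 0))
  k <- colSums(h$states)
  pi_total <- sum(k * (n - k)) / choose(n, 2)
  list(pi_total = pi_total, pi_per_site = pi_total / length_bp)
}

# Tajima (1989) normalization constants for sample size n (haplotypes).
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and Watterson
#' estimators of the population mutation rate,
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`, computed on the pooled
#' haplotype sample. Negative values indicate an excess of rare variants, the
#' footprint of a hard selective sweep (or population expansion).
#'
#' @param h a [haplotype_matrix()]
#' @return list with `D`, `S` (segregating sites), `pi_total`, `theta_w`
#'   (Watterson estimator `S/a1`), `n`. A monomorphic region gives `D = NaN`
#'   with attribute `flag = "monomorphic region"`.
#' @export
tajimas_d <- function(h) {
  n <- n_haplotypes(h)
  if (n < 4L) stop("Tajima's D requires at least 4 haplotypes")
  k <- colSums(h$states)
  seg <- k > 0L & k < n
  S <- sum(seg)
  cst <- tajima_constants(n)
  if (S == 0L) {
    out <- list(D = NaN, S = 0L, pi_total = 0, theta_w = 0, n = n)
    attr(out, "flag") <- "monomorphic region"
    return(out)
  }
  pi_total <- sum(k[seg] * (n - k[seg])) / choose(n, 2)
  theta_w <- S / cst$a1
  D <- (pi_total - theta_w) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  list(D = D, S = S, pi_total = pi_total, theta_w = theta_w, n = n)
}
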