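#' Haplotype frequency spectrum and the H12 statistic
#'
#' Groups haplotypes by exact identity over all retained sites of the region,
#' sorts the haplotype frequencies `p1 >= p2 >= ...` and computes the
#' homozygosity statistics `H1 = sum(pi^2)` and
#' `H12 = (p1 + p2)^2 + sum_{i>=3} pi^2 = H1 + 2 p1 p2`. Pooling the two most
#' frequent haplotypes makes H12 sensitive to soft sweeps, where two or more
#' independent haplotypes rise in frequency together.
#'
#' @param h a [haplotype_matrix()]; a 0-site region collapses every haplotype
#'   to the empty haplotype (`H12 = 1`, with a warning)
#' @return list with `frequencies` (sorted descending), `H1`, `H12`
#' @export
h12 <- function(h) {
  n <- n_haplotypes(h)
  if (n < 1L) stop("no haplotypes")
  if (ncol(h$states) == 0L) {
    warning("0-site region: all haplotypes identical by convention, H12 = 1")
    return(list(frequencies = 1, H1 = 1, H12 = 1))
  }
  key <- apply(h$states, 1L, paste, collapse = "")
  p <- sort(as.vector(table(key)) / n, decreasing = TRUE)
  H1 <- sum(p^2)
  p2 <- if (length(p) > 1L) p[2L] else 0
  list(frequencies = p, H1 = H1, H12 = H1 + 2 * p[1L] * p2)
}

#' Per-site nSL scores
#'
#' The "number of segregating sites by length" statistic. For every site
#' passing the minor-allele-frequency cutoff, haplotypes are partitioned by
#' the allele they carry at the focal site. For each pair of haplotypes in the
#' same class, the shared tract is the run of consecutive segregating sites
#' (counting the focal site) over which the pair is identical, extended in
#' both directions to the first mismatch, truncated at the matrix edges and
#' capped at `max_extend` sites on each side. `SL_A` and `SL_D` are the mean
#' pairwise tract lengths in the ancestral and derived class, and
#' `nsl = log(SL_A / SL_D)` (unstandardized). Elevated `|nsl|` indicates one
#' unusually long common haplotype, the footprint of a recent sweep.
#'
#' Sites with unknown polarity are skipped (the statistic needs to know which
#' allele is derived); sites where either allele class has fewer than two
#' haplotypes are skipped as well.
#'
#' @param h a [haplotype_matrix()], typically restricted to one population
#'   over the gene +/- flank window
#' @param maf_cutoff minimum minor allele frequency for a site to be scored
#'   (study default 0.01)
#' @param max_extend cap on tract extension, in segregating sites per side
#'   (default 100, the scan tool's default)
#' @return data.frame with columns `position`, `daf` (derived allele
#'   frequency), `SL_A`, `SL_D`, `nsl`; zero rows when fewer than 2 sites
#' @export
nsl_scores <- function(h, maf_cutoff = 0.01, max_extend = 100L) {
  n <- n_haplotypes(h)
  S <- ncol(h$states)
  empty <- data.frame(position = integer(0), daf = numeric(0),
                      SL_A = numeric(0), SL_D = numeric(0), nsl = numeric(0))
  if (S < 2L || n < 4L) return(empty)
  res <- nsl_pairwise_cpp(t(h$states), as.integer(max_extend))
  d <- colSums(h$states)
  daf <- d / n
  maf <- pmin(daf, 1 - daf)
  ok <- h$polarity & maf >= maf_cutoff & d >= 2L & (n - d) >= 2L
  if (!any(ok)) return(empty)
  SL_D <- res$sum_d[ok] / choose(d[ok], 2)
  SL_A <- res$sum_a[ok] / choose(n - d[ok], 2)
  data.frame(position = h$positions[ok], daf = daf[ok],
             SL_A = SL_A, SL_D = SL_D, nsl = log(SL_A / SL_D))
}

#' Window summary of nSL
#'
#' The study's per-gene summary: the maximum of `|nsl|` over all scored sites
#' in the gene +/- flank window.
#'
#' @param scores a data.frame from [nsl_scores()]
#' @return a single number; `NaN` for an empty score list
#' @export
max_abs_nsl <- function(scores) {
  if (nrow(scores) == 0L) return(NaN)
  max(abs(scores$nsl))
}
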