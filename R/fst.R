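#' Weir-Cockerham fixation index
#'
#' Variance-components estimator of population differentiation (Weir &
#' Cockerham 1984) applied to haplotypes: each haplotype is treated as a
#' haploid individual, so the within-individual heterozygosity term vanishes
#' and the per-site components reduce to `a` (among populations), `b` (among
#' haplotypes within populations) and `c = 0`. Two genome-wide summaries are
#' returned: the weighted (ratio-of-sums) estimate
#' `sum(a) / sum(a + b + c)` and the mean of per-site ratios over sites
#' polymorphic in the pooled sample.
#'
#' @param h a [haplotype_matrix()] carrying population labels
#' @param mode `"global"` for the single k-population estimate, `"pairwise"`
#'   for all population pairs
#' @return for `mode = "global"`, a list with `fst_weighted`, `fst_mean`,
#'   `n_sites_used`; for `mode = "pairwise"`, a data.frame with one row per
#'   unordered pair (`pop1`, `pop2`, `fst_weighted`, `fst_mean`)
#' @export
wc_fst <- function(h, mode = c("global", "pairwise")) {
  mode <- match.arg(mode)
  pops <- sort(unique(h$pop_labels))
  if (length(pops) < 2L) stop("FST requires at least 2 populations")
  sizes <- table(h$pop_labels)
  if (any(sizes < 2L))
    stop("every population needs at least 2 haplotypes; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (mode == "pairwise") {
    pairs <- utils::combn(pops, 2L)
    out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      sub <- subset_population(h, pairs[, j])
      g <- wc_fst(sub, mode = "global")
      data.frame(pop1 = pairs[1L, j], pop2 = pairs[2L, j],
                 fst_weighted = g$fst_weighted, fst_mean = g$fst_mean,
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }
  comp <- wc_components(h$states, h$pop_labels)
  tot <- comp$a + comp$b + comp$c
  poly <- comp$polymorphic
  if (!any(poly))
    return(list(fst_weighted = NaN, fst_mean = NaN, n_sites_used = 0L))
  fst_weighted <- sum(comp$a[poly]) / sum(tot[poly])
  fst_mean <- mean(comp$a[poly] / tot[poly])
  list(fst_weighted = fst_weighted, fst_mean = fst_mean,
       n_sites_used = sum(poly))
}

# Per-site Weir-Cockerham (1984) variance components for haploid samples,
# vectorized over sites. r populations, n_i haplotypes each; hbar = 0.
wc_components <- function(states, labels) {
  pops <- sort(unique(labels))
  r <- length(pops)
  ni <- vapply(pops, function(p) sum(labels == p), numeric(1))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  # per-pop allele-1 frequencies at every site: r x S
  pmat <- do.call(rbind, lapply(pops, function(p)
    colMeans(states[labels == p, , drop = FALSE])))
  pbar <- colSums(ni * pmat) / (r * nbar)
  s2 <- colSums(ni * sweep(pmat, 2L, pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  list(a = a, b = b, c = rep(0, length(a)),
       polymorphic = pbar > 0 & pbar < 1)
}
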