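#' Phased haplotype matrix
#'
#' The central container of the package: a haplotype-by-site matrix of 0/1
#' allele states for a set of phased diploid samples, together with physical
#' positions, per-site ancestral-state polarity, and per-haplotype sample and
#' population annotation. Rows come in pairs (two haplotypes per sample);
#' columns are segregating sites in strictly increasing position order.
#'
#' @param states integer or numeric matrix of 0/1 states, rows = haplotypes,
#'   columns = sites. Missing values are not permitted.
#' @param positions integer vector of 1-based physical positions (bp), one per
#'   column, strictly increasing.
#' @param chrom single chromosome label.
#' @param polarity logical vector, one per column: `TRUE` when the 1 allele is
#'   known to be the derived allele, `FALSE` when polarity is unknown.
#'   Recycled from length 1.
#' @param sample_ids character vector of originating sample ids, one per row
#'   (each id appearing exactly twice, on consecutive rows).
#' @param pop_labels character vector of population codes, one per row.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `states`, `positions`, `chrom`, `polarity`, `sample_ids`, `pop_labels`.
#' @export
haplotype_matrix <- function(states, positions, chrom = "1",
                             polarity = TRUE,
                             sample_ids = NULL, pop_labels = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (anyNA(states)) stop("missing haplotype states are not permitted")
  if (length(states) && !all(states %in% c(0L, 1L)))
    stop("haplotype states must be 0 or 1")
  if (nrow(states) %% 2L != 0L)
    stop("haplotype count must be even (two haplotypes per diploid sample)")
  positions <- as.integer(positions)
  if (length(positions) != ncol(states))
    stop("length(positions) must equal the number of sites")
  if (ncol(states) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  polarity <- rep_len(as.logical(polarity), ncol(states))
  n_sam <- nrow(states) %/% 2L
  if (is.null(sample_ids))
    sample_ids <- rep(sprintf("S%d", seq_len(max(n_sam, 1L))), each = 2L)[
      seq_len(nrow(states))]
  if (is.null(pop_labels))
    pop_labels <- rep("POP1", nrow(states))
  if (length(sample_ids) != nrow(states) || length(pop_labels) != nrow(states))
    stop("sample_ids and pop_labels must have one entry per haplotype row")
  structure(
    list(states = states, positions = positions, chrom = as.character(chrom),
         polarity = polarity, sample_ids = as.character(sample_ids),
         pop_labels = as.character(pop_labels)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d samples) x %d sites on %s\n",
              nrow(x$states), nrow(x$states) %/% 2L, ncol(x$states), x$chrom))
  if (ncol(x$states))
    cat(sprintf("  positions %d..%d; %d/%d sites polarized\n",
                min(x$positions), max(x$positions),
                sum(x$polarity), length(x$polarity)))
  tb <- table(x$pop_labels[c(TRUE, FALSE)])
  cat("  samples per population:",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of haplotypes / sites
#' @param h a [haplotype_matrix()]
#' @return integer count
#' @export
n_haplotypes <- function(h) nrow(h$states)

#' @rdname n_haplotypes
#' @export
n_sites <- function(h) ncol(h$states)

#' Subset a haplotype matrix by population
#'
#' Restricts the rows to the haplotypes whose population label is in `pops`.
#' Sites, positions and polarity are untouched, so per-population statistics
#' computed on the result are identical to computing on the full matrix
#' restricted to those rows.
#'
#' @param h a [haplotype_matrix()]
#' @param pops character vector of population codes to keep
#' @return a [haplotype_matrix()] with the selected rows
#' @export
subset_population <- function(h, pops) {
  keep <- h$pop_labels %in% pops
  if (!any(keep)) stop("no haplotypes with population label(s): ",
                       paste(pops, collapse = ", "))
  haplotype_matrix(h$states[keep, , drop = FALSE], h$positions, h$chrom,
                   h$polarity, h$sample_ids[keep], h$pop_labels[keep])
}

#' Subset a haplotype matrix by site index
#' @param h a [haplotype_matrix()]
#' @param idx integer site (column) indices to keep, in increasing order
#' @return a [haplotype_matrix()]
#' @export
subset_sites <- function(h, idx) {
  haplotype_matrix(h$states[, idx, drop = FALSE], h$positions[idx], h$chrom,
                   h$polarity[idx], h$sample_ids, h$pop_labels)
}

#' Restrict a haplotype matrix to a genomic interval
#' @param h a [haplotype_matrix()]
#' @param start,end 1-based inclusive interval bounds (bp)
#' @return a [haplotype_matrix()] containing the sites inside the interval
#' @export
subset_interval <- function(h, start, end) {
  subset_sites(h, which(h$positions >= start & h$positions <= end))
}
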