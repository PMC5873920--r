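#' Empirical p-value against a simulated null
#'
#' The proportion of null values equal to or more extreme than the observed
#' value. Tails: `"upper"` counts `null >= obs`, `"lower"` counts
#' `null <= obs`, and `"two_sided_abs"` counts values at least as far from
#' the null median as the observation.
#'
#' @param observed observed statistic value
#' @param null a [null_distribution()] object or a numeric vector of valid
#'   null values
#' @param tail one of `"upper"`, `"lower"`, `"two_sided_abs"`
#' @return p-value in `[0, 1]`; `NaN` when `observed` is `NaN`/`NA`
#' @export
empirical_pvalue <- function(observed,
                             null,
                             tail = c("upper", "lower", "two_sided_abs")) {
  tail <- match.arg(tail)
  vals <- if (inherits(null, "null_distribution")) null$values else null
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("null distribution has no valid values")
  if (is.na(observed)) return(NaN)
  switch(tail,
    upper = mean(vals >= observed),
    lower = mean(vals <= observed),
    two_sided_abs = {
      m <- stats::median(vals)
      mean(abs(vals - m) >= abs(observed - m))
    })
}

#' Default tail convention per statistic
#'
#' Tajima's D is tested two-sided around the null median (sweep-like negative
#' and balancing-like positive values are both extreme); FST, H12 and
#' max|nSL| are upper-tailed, since only elevation signals selection.
#'
#' @param statistic statistic name
#' @return a tail keyword accepted by [empirical_pvalue()]
#' @export
default_tail <- function(statistic) {
  switch(statistic,
         tajimas_d = "two_sided_abs",
         fst = , h12 = , nsl_max = "upper",
         stop("no p-value convention for statistic: ", statistic))
}

#' Scan genes for selection signatures
#'
#' For each gene: pi (descriptive, no p-value), Tajima's D on the pooled
#' sample (two-sided), global weighted FST (upper tail), H12 on the pooled
#' sample (upper tail) and the per-population maximum |nSL| over the gene
#' +/- flank window (upper tail). Each statistic is compared to the matched
#' null distribution (same statistic, region length and scope).
#'
#' @param genes gene table (data.frame with `name`, `chrom`, `start`, `end`,
#'   `category`)
#' @param hap_source function `(chrom, start, end) -> haplotype_matrix` that
#'   yields the observed haplotypes for an interval
#' @param nulls an environment or named list of [null_distribution()]
#'   objects keyed by `"<statistic>:<length_bp>:<scope>"`
#' @param alpha significance cutoff (default 0.05)
#' @param flank_bp nSL window flank in bp (default 100000)
#' @param maf_cutoff nSL MAF cutoff (default 0.01)
#' @param populations populations for the per-population nSL scan
#' @return data.frame of class `scan_result`: one row per gene x statistic
#'   with `observed`, `n_valid_null`, `p_value`, `significant`
#' @export
scan_genes <- function(genes, hap_source, nulls, alpha = 0.05,
                       flank_bp = 1e5, maf_cutoff = 0.01,
                       populations = c("AFR", "EUR", "EAS")) {
  get_null <- function(statistic, len, scope) {
    key <- null_key(statistic, len, scope)
    nd <- if (is.environment(nulls)) {
      if (exists(key, envir = nulls, inherits = FALSE))
        get(key, envir = nulls) else NULL
    } else nulls[[key]]
    nd
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start + 1L
    h <- hap_source(g$chrom, g$start, g$end)
    wlen <- len + 2L * flank_bp
    one <- function(statistic, scope, observed, tail, descriptive = FALSE) {
      if (descriptive)
        return(data.frame(gene = g$name, category = g$category,
                          statistic = statistic, scope = scope,
                          observed = observed, n_valid_null = NA_integer_,
                          p_value = NA_real_, significant = NA,
                          stringsAsFactors = FALSE))
      use_len <- if (statistic == "nsl_max") wlen else len
      nd <- get_null(statistic, use_len, scope)
      if (is.null(nd))
        stop(sprintf("missing null distribution for gene %s (%s, length %d, scope %s)",
                     g$name, statistic, use_len, scope))
      p <- empirical_pvalue(observed, nd, tail)
      data.frame(gene = g$name, category = g$category, statistic = statistic,
                 scope = scope, observed = observed,
                 n_valid_null = length(nd$values), p_value = p,
                 significant = if (is.na(p)) NA else p < alpha,
                 stringsAsFactors = FALSE)
    }
    out <- list(
      one("pi", "pooled", nucleotide_diversity(h, len)$pi_per_site,
          NULL, descriptive = TRUE),
      one("tajimas_d", "pooled", tajimas_d(h)$D, "two_sided_abs"),
      one("fst", "global", wc_fst(h, "global")$fst_weighted, "upper"),
      one("h12", "pooled", suppressWarnings(h12(h)$H12), "upper"))
    hw <- hap_source(g$chrom, max(1L, g$start - flank_bp), g$end + flank_bp)
    for (pop in populations) {
      obs <- max_abs_nsl(nsl_scores(subset_population(hw, pop),
                                    maf_cutoff = maf_cutoff))
      out[[length(out) + 1L]] <- one("nsl_max", pop, obs, "upper")
    }
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Key under which a null distribution is cached
#' @param statistic,length_bp,scope the null's identity
#' @return a string
#' @export
null_key <- function(statistic, length_bp, scope) {
  sprintf("%s:%d:%s", statistic, as.integer(length_bp), scope)
}

#' Human-readable p-value string
#'
#' Empirical p-values of exactly zero are displayed as `< 1/n` to flag the
#' resolution limit of the simulated null; the stored value remains 0.
#'
#' @param p p-value
#' @param n_valid null sample size
#' @return character
#' @export
format_pvalue <- function(p, n_valid) {
  ifelse(is.na(p), "NA",
         ifelse(p == 0, sprintf("< %g", 1 / n_valid), sprintf("%g", p)))
}
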