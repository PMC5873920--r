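#' @importFrom data.table fread
NULL

POP_CODES <- c("AFR", "EUR", "EAS")

GENE_CATEGORIES <- c("biosynthesis", "activation_transport_transfer",
                     "recognition", "recycling_degradation")

#' Read a sample-to-population panel
#'
#' Reads a two-column TSV mapping sample ids to population codes
#' (`AFR`, `EUR`, `EAS`). A header line is detected automatically.
#'
#' @param path path to the TSV file
#' @param verbose print per-population counts (default `TRUE`)
#' @return a data.frame with columns `sample_id`, `population`, of class
#'   `population_panel`
#' @export
read_panel <- function(path, verbose = TRUE) {
  tab <- data.table::fread(path, header = "auto", sep = "\t",
                           colClasses = "character", data.table = FALSE)
  if (nrow(tab) == 0L) stop("no samples in panel file: ", path)
  if (ncol(tab) < 2L) stop("panel file must have two columns (sample_id, population)")
  tab <- tab[, 1:2]
  names(tab) <- c("sample_id", "population")
  dup <- duplicated(tab$sample_id)
  if (any(dup))
    stop("duplicate sample_id in panel: ",
         paste(unique(tab$sample_id[dup]), collapse = ", "))
  bad <- !(tab$population %in% POP_CODES)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("unknown population code '%s' for sample '%s' (row %d)",
                 tab$population[i], tab$sample_id[i], i))
  }
  if (verbose) {
    cnt <- table(factor(tab$population, levels = POP_CODES))
    message("panel: ", nrow(tab), " samples (",
            paste(sprintf("%s=%d", names(cnt), as.integer(cnt)),
                  collapse = ", "), ")")
  }
  class(tab) <- c("population_panel", "data.frame")
  tab
}

#' Construct a gene region record
#'
#' @param name gene symbol
#' @param chrom chromosome label
#' @param start,end 1-based inclusive bounds (bp), `start <= end`
#' @param category one of the four functional categories:
#'   `r paste(GENE_CATEGORIES, collapse = ", ")`
#' @return a one-row data.frame of class `gene_region`
#' @export
gene_region <- function(name, chrom, start, end, category) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop(sprintf("gene %s: start (%s) must be <= end (%s)", name, start, end))
  if (!category %in% GENE_CATEGORIES)
    stop(sprintf("gene %s: unknown category '%s'", name, category))
  structure(data.frame(name = name, chrom = as.character(chrom),
                       start = start, end = end, category = category,
                       stringsAsFactors = FALSE),
            class = c("gene_region", "data.frame"))
}

#' Read a gene coordinate table
#'
#' Reads a TSV with columns `name`, `chrom`, `start`, `end`, `category`
#' (1-based inclusive coordinates) and optionally extra annotation columns
#' such as `pseudogene`. With `strict = TRUE` (default) any category outside
#' the four-value set is an error; `strict = FALSE` admits arbitrary category
#' strings, which is useful for raw candidate lists that still have to pass
#' through [apply_gene_filters()].
#'
#' @param path path to the TSV file
#' @param strict validate categories against the four-value set
#' @return data.frame with one row per gene, input order preserved
#' @export
read_gene_table <- function(path, strict = TRUE) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("name", "chrom", "start", "end", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- tab$start > tab$end
  if (any(bad))
    stop("start > end for gene(s): ", paste(tab$name[bad], collapse = ", "))
  if (strict) {
    unk <- !(tab$category %in% GENE_CATEGORIES)
    if (any(unk))
      stop(sprintf("unknown category '%s' for gene '%s'",
                   tab$category[which(unk)[1L]], tab$name[which(unk)[1L]]))
  }
  if ("pseudogene" %in% names(tab))
    tab$pseudogene <- as.logical(tab$pseudogene)
  tab
}

#' Apply the study's gene-level exclusion filters
#'
#' Removes genes on the X chromosome (sex-linked loci show different patterns
#' of variation than autosomes) and genes flagged as pseudogenes. Returns the
#' retained genes plus an exclusion log.
#'
#' @param genes data.frame as returned by [read_gene_table()]; an optional
#'   logical `pseudogene` column marks non-functional loci (absent = all
#'   `FALSE`)
#' @return list with elements `retained` (data.frame, input order) and
#'   `excluded` (data.frame with columns `name`, `reason`)
#' @export
apply_gene_filters <- function(genes) {
  pseudo <- if ("pseudogene" %in% names(genes)) {
    g <- genes$pseudogene
    g[is.na(g)] <- FALSE
    g
  } else rep(FALSE, nrow(genes))
  xlinked <- toupper(sub("^chr", "", genes$chrom)) == "X"
  reason <- character(nrow(genes))
  reason[pseudo] <- "pseudogene"
  reason[xlinked] <- ifelse(pseudo[xlinked], "X-linked;pseudogene", "X-linked")
  drop <- xlinked | pseudo
  list(retained = genes[!drop, , drop = FALSE],
       excluded = data.frame(name = genes$name[drop],
                             reason = reason[drop],
                             stringsAsFactors = FALSE))
}
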