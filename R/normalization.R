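## Size factors: per-sample positive scalars correcting for library-size
## differences; junction counts and coverage are divided by them.

#' Median-of-ratios size factors from per-region coverage summaries
#'
#' The reference for each region is the geometric mean of its summaries over
#' samples (regions containing any zero are excluded); a sample's factor is
#' the median over regions of summary/reference. Factors are rescaled to
#' geometric mean 1, which makes them identifiable.
#'
#' @param summaries numeric matrix, regions (e.g. meta-exons) x samples, of
#'   total coverage sums.
#' @return An object of class `size_factors`: named positive numeric vector
#'   with attribute `method = "median_ratio"`.
#' @export
estimate_size_factors <- function(summaries) {
  summaries <- as.matrix(summaries)
  if (ncol(summaries) < 2L) stop("need >= 2 samples to estimate size factors")
  pos <- rowSums(summaries <= 0) == 0L
  if (sum(pos) < 2L)
    stop("fewer than 2 regions with all-positive coverage; ",
         "consider supplying size factors via the project file")
  lm <- log(summaries[pos, , drop = FALSE])
  ref <- rowMeans(lm)                      # log geometric mean per region
  f <- exp(apply(lm - ref, 2L, median))    # median of ratios
  f <- f / exp(mean(log(f)))               # geometric mean 1
  structure(setNames(f, colnames(summaries)),
            method = "median_ratio", class = "size_factors")
}

#' Wrap user-supplied size factors
#'
#' @param factors named positive numeric vector (names = sample ids).
#' @return A `size_factors` object with `method = "user_supplied"`.
#' @export
user_size_factors <- function(factors) {
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  structure(factors, method = "user_supplied", class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat("size_factors (", attr(x, "method"), "):\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Divide per-sample values by their size factors
#'
#' @param values numeric matrix (columns = samples) or vector (one value per
#'   sample).
#' @param size_factors one positive factor per sample column.
#' @return `values` with each sample divided by its factor.
#' @export
adjust <- function(values, size_factors) {
  sf <- as.numeric(size_factors)
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors must be positive and finite")
  if (is.matrix(values)) {
    if (ncol(values) != length(sf))
      stop("one size factor per sample column required")
    sweep(values, 2L, sf, `/`)
  } else {
    if (length(values) != length(sf))
      stop("one size factor per sample required")
    values / sf
  }
}

#' Per-meta-exon coverage sums for size-factor estimation
#'
#' @param gene a [gene_model].
#' @param coverage a `coverage_set` over the gene span (raw, unadjusted).
#' @return numeric matrix meta-exons x samples of coverage sums.
#' @export
meta_exon_coverage_sums <- function(gene, coverage) {
  metas <- build_meta_exons(gene)
  out <- matrix(0, nrow(metas), length(coverage$samples),
                dimnames = list(NULL, coverage$samples))
  for (i in seq_len(nrow(metas))) {
    rows <- (metas$start[i] - coverage$start + 1L):(metas$end[i] - coverage$start)
    out[i, ] <- colSums(coverage$mat[rows, , drop = FALSE])
  }
  out
}

#' Size factors for a project
#'
#' Uses the project's `size_factor` column when complete; otherwise
#' estimates median-of-ratios factors from per-meta-exon coverage sums over
#' the supplied genes.
#'
#' @param project a `project_config`.
#' @param genes list of [gene_model]s whose loci provide the coverage
#'   summaries.
#' @return A `size_factors` object, one factor per project sample.
#' @export
project_size_factors <- function(project, genes) {
  if (!anyNA(project$size_factor))
    return(user_size_factors(setNames(project$size_factor, project$sample)))
  if (inherits(genes, "gene_model")) genes <- list(genes)
  summ <- do.call(rbind, lapply(genes, function(g) {
    cov <- read_coverage(setNames(project$bigwig, project$sample),
                         g$chrom, g$start, g$end, project$condition)
    meta_exon_coverage_sums(g, cov)
  }))
  estimate_size_factors(summ)
}
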