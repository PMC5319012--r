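## Per-sample junction count files, coverage tracks and project metadata.
##
## Junction dialects:
##  * star_sj      -- STAR SJ.out.tab: chrom, intron first base (1-based),
##                    intron last base (1-based), strand (0/1/2), motif,
##                    annotated, unique reads, multi reads, max overhang.
##                    The unique-read column is used as the count.
##  * minimal_tsv  -- chrom, donor_end, acceptor_start, count; already
##                    0-based (donor_end = intron start, acceptor_start =
##                    first base of the downstream exon).

#' Read one per-sample junction count file
#'
#' @param path file path.
#' @param dialect `"star_sj"` or `"minimal_tsv"`.
#' @return data.frame with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `strand` (`"+"`, `"-"` or `"*"` when undefined), `count`.
#' @export
read_junction_file <- function(path, dialect = c("minimal_tsv", "star_sj")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction file not found: ", path)
  empty <- data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character(),
                      count = numeric())
  if (file.size(path) == 0L) return(empty)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (dialect == "star_sj") {
    if (ncol(tab) < 7L)
      stop("STAR SJ.out.tab '", path, "': expected >= 7 columns, got ", ncol(tab))
    out <- data.frame(chrom = as.character(tab[[1L]]),
                      donor_end = as.integer(tab[[2L]]) - 1L,
                      acceptor_start = as.integer(tab[[3L]]),
                      strand = c("*", "+", "-")[as.integer(tab[[4L]]) + 1L],
                      count = as.numeric(tab[[7L]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(tab) != 4L)
      stop("minimal junction TSV '", path, "': expected 4 columns, got ", ncol(tab))
    out <- data.frame(chrom = as.character(tab[[1L]]),
                      donor_end = as.integer(tab[[2L]]),
                      acceptor_start = as.integer(tab[[3L]]),
                      strand = "*", count = as.numeric(tab[[4L]]),
                      stringsAsFactors = FALSE)
  }
  if (anyNA(out$donor_end) || anyNA(out$acceptor_start) || anyNA(out$count))
    stop("junction file '", path, "': non-numeric coordinate or count")
  if (any(out$count < 0))
    stop("junction file '", path, "': negative count")
  if (any(out$donor_end >= out$acceptor_start))
    stop("junction file '", path, "': junction with donor_end >= acceptor_start")
  out
}

#' Merge per-sample junction lists into one indexed table
#'
#' Takes the union of junctions over all samples (keyed by chrom, donor_end,
#' acceptor_start); a sample without a given junction contributes count 0.
#' Junctions with zero counts in every sample are dropped. Each junction is
#' flagged `known` by membership among the annotation's introns; junctions
#' with undefined strand inherit the strand of a matching annotated intron,
#' or the gene strand if they fall within a single annotated gene.
#'
#' @param per_sample named list (names = sample ids) of data.frames as
#'   returned by [read_junction_file()].
#' @param annotation optional [gene_model] or list of gene models used for
#'   the `known` flag and strand inference.
#' @return An object of class `junction_table`: list with `junctions`
#'   (data.frame `chrom`, `donor_end`, `acceptor_start`, `strand`, `known`),
#'   `counts` (matrix junction x sample, column order = input order) and
#'   `samples`.
#' @export
merge_junction_tables <- function(per_sample, annotation = NULL) {
  stopifnot(length(per_sample) >= 1L)
  samples <- names(per_sample)
  if (is.null(samples) || any(samples == ""))
    stop("per_sample must be a named list (sample ids)")
  all <- do.call(rbind, lapply(samples, function(s) {
    d <- per_sample[[s]]
    if (nrow(d) == 0L) return(NULL)
    cbind(d, sample = s)
  }))
  if (is.null(all) || nrow(all) == 0L) {
    junc <- data.frame(chrom = character(), donor_end = integer(),
                       acceptor_start = integer(), strand = character(),
                       known = logical())
    counts <- matrix(0, 0L, length(samples),
                     dimnames = list(NULL, samples))
    return(structure(list(junctions = junc, counts = counts,
                          samples = samples), class = "junction_table"))
  }
  key <- paste(all$chrom, all$donor_end, all$acceptor_start, sep = ":")
  ukey <- sort(unique(key))
  counts <- matrix(0, length(ukey), length(samples),
                   dimnames = list(ukey, samples))
  lin <- (match(all$sample, samples) - 1L) * length(ukey) + match(key, ukey)
  sums <- rowsum(all$count, group = lin)   # sums duplicates within a file
  counts[as.integer(rownames(sums))] <- sums[, 1L]
  first <- all[!duplicated(key), ]
  first <- first[match(ukey, paste(first$chrom, first$donor_end,
                                   first$acceptor_start, sep = ":")), ]
  junc <- data.frame(chrom = first$chrom, donor_end = first$donor_end,
                     acceptor_start = first$acceptor_start,
                     strand = first$strand, known = FALSE,
                     stringsAsFactors = FALSE)
  ## strand conflict across samples -> undefined
  str_by_key <- tapply(all$strand, key, function(s) {
    s <- setdiff(unique(s), "*")
    if (length(s) == 1L) s else "*"
  })
  junc$strand <- as.character(str_by_key[ukey])
  if (!is.null(annotation)) {
    genes <- if (inherits(annotation, "gene_model")) list(annotation) else annotation
    intr <- gene_introns(genes)
    m <- match(paste(junc$chrom, junc$donor_end, junc$acceptor_start),
               paste(intr$chrom, intr$donor_end, intr$acceptor_start))
    junc$known <- !is.na(m)
    take <- junc$strand == "*" & !is.na(m)
    junc$strand[take] <- intr$strand[m][take]
    ## novel junctions inside exactly one gene inherit its strand
    und <- which(junc$strand == "*")
    for (i in und) {
      hits <- vapply(genes, function(g)
        g$chrom == junc$chrom[i] && junc$donor_end[i] >= g$start &&
          junc$acceptor_start[i] <= g$end, logical(1L))
      if (sum(hits) == 1L) junc$strand[i] <- genes[[which(hits)]]$strand
    }
  }
  keep <- rowSums(counts) > 0
  junc <- junc[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  ord <- order(junc$chrom, junc$donor_end, junc$acceptor_start)
  junc <- junc[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  rownames(junc) <- rownames(counts) <- NULL
  structure(list(junctions = junc, counts = counts, samples = samples),
            class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("junction_table: %d junction(s) x %d sample(s)\n",
              nrow(x$junctions), length(x$samples)))
  invisible(x)
}

#' Query junctions fully contained in a genomic range
#'
#' Returns the junctions whose intron lies entirely inside
#' `[start, end)` on `chrom` (both `donor_end` and `acceptor_start` within
#' the range).
#'
#' @param table a `junction_table`.
#' @param chrom chromosome.
#' @param start,end 0-based half-open query range.
#' @return list with `junctions` (subset data.frame) and `counts` (matching
#'   count matrix rows).
#' @export
query_junctions <- function(table, chrom, start, end) {
  j <- table$junctions
  sel <- which(j$chrom == chrom & j$donor_end >= start & j$acceptor_start <= end)
  list(junctions = j[sel, , drop = FALSE],
       counts = table$counts[sel, , drop = FALSE])
}

#' Read per-sample per-base coverage over a gene span
#'
#' Accepts bigwig (`.bw`, `.bigwig`) and bedgraph (`.bedgraph`, `.bg`)
#' tracks; both yield identical dense arrays for identical data. Bases
#' without track data are 0.
#'
#' @param paths named character vector of track paths (names = sample ids).
#' @param chrom chromosome of the span.
#' @param start,end 0-based half-open span.
#' @param conditions character vector of condition labels, parallel to
#'   `paths`.
#' @return An object of class `coverage_set`: list with `chrom`, `start`,
#'   `end`, `mat` (numeric matrix of `end - start` rows x samples),
#'   `samples`, `conditions`.
#' @export
read_coverage <- function(paths, chrom, start, end, conditions) {
  stopifnot(length(paths) == length(conditions), end > start)
  samples <- names(paths)
  if (is.null(samples)) stop("paths must be named by sample id")
  mat <- matrix(0, end - start, length(paths),
                dimnames = list(NULL, samples))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    gr <- tryCatch(import_track(p, chrom, start, end),
                   error = function(e)
                     stop("cannot read coverage for sample '", samples[i],
                          "' from '", p, "': ", conditionMessage(e)))
    mat[, i] <- densify_track(gr, chrom, start, end)
  }
  structure(list(chrom = chrom, start = start, end = end, mat = mat,
                 samples = samples, conditions = as.character(conditions)),
            class = "coverage_set")
}

import_track <- function(path, chrom, start, end) {
  if (!file.exists(path)) stop("file not found")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
    rtracklayer::import(path, format = "BigWig", which = which)
  } else if (ext %in% c("bedgraph", "bg")) {
    if (file.size(path) == 0L) return(GenomicRanges::GRanges())
    rtracklayer::import(path, format = "bedGraph")
  } else stop("unsupported track format '.", ext, "'")
}

densify_track <- function(gr, chrom, start, end) {
  v <- numeric(end - start)
  if (length(gr) == 0L) return(v)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  s <- pmax(GenomicRanges::start(gr) - 1L, start)  # to 0-based
  e <- pmin(GenomicRanges::end(gr), end)
  keep <- s < e
  s <- s[keep]; e <- e[keep]; sc <- gr$score[keep]
  for (k in seq_along(s))
    v[(s[k] - start + 1L):(e[k] - start)] <- sc[k]
  v
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("coverage_set %s:%d-%d, %d sample(s), conditions: %s\n",
              x$chrom, x$start, x$end, length(x$samples),
              paste(unique(x$conditions), collapse = ", ")))
  invisible(x)
}

#' Read a project file
#'
#' Tab-separated with a header; required columns `sample`, `condition`,
#' `bigwig` (coverage track path; bedgraph accepted), `junctions` (junction
#' count file path); optional `size_factor`. Relative paths are resolved
#' against the project file's directory.
#'
#' @param path project TSV path.
#' @return data.frame, one row per sample, with class `project_config`.
#' @export
read_project <- function(path) {
  if (!file.exists(path)) stop("project file not found: ", path)
  pr <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample", "condition", "bigwig", "junctions")
  miss <- setdiff(need, names(pr))
  if (length(miss))
    stop("project file '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(pr$sample))
    stop("project file: duplicated sample ids")
  if (anyDuplicated(pr$bigwig) || anyDuplicated(pr$junctions))
    stop("project file: per-sample file paths must be distinct")
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  pr$bigwig <- resolve(pr$bigwig)
  pr$junctions <- resolve(pr$junctions)
  if (!"size_factor" %in% names(pr)) pr$size_factor <- NA_real_
  class(pr) <- c("project_config", "data.frame")
  pr
}

#' Load junction counts and coverage for a gene from a project
#'
#' @param project a `project_config` from [read_project()].
#' @param gene a [gene_model].
#' @param annotation optional annotation (list of gene models) for `known`
#'   flags; defaults to the gene itself.
#' @param dialect junction file dialect, see [read_junction_file()].
#' @return list with `table` (a `junction_table` restricted to the gene
#'   span) and `coverage` (a `coverage_set` over the gene span).
#' @export
load_gene_data <- function(project, gene, annotation = NULL,
                           dialect = "minimal_tsv") {
  if (is.null(annotation)) annotation <- list(gene)
  per_sample <- setNames(lapply(project$junctions, read_junction_file,
                                dialect = dialect), project$sample)
  tab <- merge_junction_tables(per_sample, annotation)
  q <- query_junctions(tab, gene$chrom, gene$start, gene$end)
  tab$junctions <- q$junctions
  tab$counts <- q$counts
  cov <- read_coverage(setNames(project$bigwig, project$sample),
                       gene$chrom, gene$start, gene$end,
                       project$condition)
  list(table = tab, coverage = cov)
}
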