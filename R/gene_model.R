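## Gene models: transcripts, exons, meta-exons, exon groups, overlaps.
## Internal coordinates are 0-based half-open throughout; GTF (1-based
## inclusive) is converted at the parse/write boundary.

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`. Unstranded genes are rejected because
#'   sense/antisense overlap classification requires a strand.
#' @param transcripts named list; each element a list with fields `id`,
#'   `exons` (data.frame with 0-based half-open `start`, `end`),
#'   `is_incomplete` (logical, default `FALSE`).
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (gene span), and `transcripts`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  if (!strand %in% c("+", "-"))
    stop("gene '", gene_id, "': strand must be '+' or '-' (unstranded annotations are not supported)")
  if (length(transcripts) < 1L)
    stop("gene '", gene_id, "': needs at least one transcript")
  transcripts <- lapply(transcripts, function(tx) {
    ex <- tx$exons
    stopifnot(is.data.frame(ex), all(c("start", "end") %in% names(ex)))
    ex <- ex[order(ex$start), c("start", "end"), drop = FALSE]
    rownames(ex) <- NULL
    if (any(ex$start >= ex$end))
      stop("transcript '", tx$id, "': exon with start >= end")
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)] + 1L))
      stop("transcript '", tx$id, "': overlapping or book-ended exons (introns must have length >= 1)")
    list(id = tx$id, exons = ex,
         is_incomplete = isTRUE(tx$is_incomplete))
  })
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  ex_all <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = min(ex_all$start), end = max(ex_all$end),
         transcripts = transcripts),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s' %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

#' All exons of a gene as one table
#'
#' @param gene a [gene_model].
#' @param transcripts optional character vector restricting to these
#'   transcript ids.
#' @return data.frame with columns `transcript_id`, `start`, `end`.
#' @export
gene_exons <- function(gene, transcripts = NULL) {
  txs <- gene$transcripts
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, names(txs))
    if (length(missing))
      stop("unknown transcript id(s): ", paste(missing, collapse = ", "))
    txs <- txs[transcripts]
  }
  out <- do.call(rbind, lapply(txs, function(tx)
    data.frame(transcript_id = tx$id, start = tx$exons$start,
               end = tx$exons$end, stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer())
  rownames(out) <- NULL
  out
}

#' Introns of a gene (annotated junctions)
#'
#' Each pair of consecutive exons of a transcript defines one intron; the
#' returned coordinates are the junction identifiers used throughout:
#' `donor_end` = 0-based start of the intron (one past the last exonic base
#' of the upstream exon), `acceptor_start` = 0-based first base of the
#' downstream exon.
#'
#' @param gene a [gene_model] or a list of gene models.
#' @return data.frame with columns `chrom`, `donor_end`, `acceptor_start`,
#'   `strand`, deduplicated.
#' @export
gene_introns <- function(gene) {
  genes <- if (inherits(gene, "gene_model")) list(gene) else gene
  rows <- lapply(genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tx) {
      ex <- tx$exons
      if (nrow(ex) < 2L) return(NULL)
      data.frame(chrom = g$chrom,
                 donor_end = ex$end[-nrow(ex)],
                 acceptor_start = ex$start[-1L],
                 strand = g$strand, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer(), strand = character()))
  out <- unique(out)
  out <- out[order(out$chrom, out$donor_end, out$acceptor_start), ]
  rownames(out) <- NULL
  out
}

#' Parse a gene from a GTF file
#'
#' Reads an Ensembl/GENCODE-style GTF (requiring `gene_id` and
#' `transcript_id` attributes on exon records) and returns the model of one
#' gene, with coordinates converted from 1-based inclusive to internal
#' 0-based half-open.
#'
#' @param path path to a GTF file.
#' @param gene_id gene to extract; if `NULL`, all genes are returned as a
#'   named list of [gene_model] objects.
#' @return A [gene_model] (or named list of them when `gene_id = NULL`).
#' @export
parse_gtf <- function(path, gene_id = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("malformed GTF '", path, "': ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("GTF '", path, "' contains no exon records")
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("GTF '", path, "': exon records must carry gene_id and transcript_id")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  build_one <- function(gid) {
    sub <- df[df$gene_id == gid, ]
    strand <- unique(sub$strand)
    if (length(strand) != 1L)
      stop("gene '", gid, "': inconsistent strand across exons")
    if (strand == "*")
      stop("gene '", gid, "': unstranded annotation is not supported")
    txs <- lapply(split(sub, sub$transcript_id), function(s)
      list(id = s$transcript_id[1L],
           exons = data.frame(start = s$start, end = s$end)))
    gene_model(gid, sub$chrom[1L], strand, txs)
  }
  if (is.null(gene_id)) {
    gids <- unique(df$gene_id)
    return(setNames(lapply(gids, build_one), gids))
  }
  if (!gene_id %in% df$gene_id)
    stop("gene id '", gene_id, "' not found in ", path)
  build_one(gene_id)
}

#' Write gene models to a GTF file
#'
#' Inverse of [parse_gtf()]: internal 0-based half-open exon coordinates are
#' written as 1-based inclusive GTF exon records (plus gene and transcript
#' lines).
#'
#' @param genes a [gene_model] or list of gene models.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  genes <- if (inherits(genes, "gene_model")) list(genes) else genes
  lines <- unlist(lapply(genes, function(g) {
    gl <- sprintf('%s\tsplicescout\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                  g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
    tl <- unlist(lapply(g$transcripts, function(tx) {
      hdr <- sprintf('%s\tsplicescout\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                     g$chrom, min(tx$exons$start) + 1L, max(tx$exons$end),
                     g$strand, g$gene_id, tx$id)
      ex <- sprintf('%s\tsplicescout\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                    g$chrom, tx$exons$start + 1L, tx$exons$end,
                    g$strand, g$gene_id, tx$id)
      c(hdr, ex)
    }))
    c(gl, tl)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Build meta-exons
#'
#' A meta-exon is the chromosomal region defined by the minimum start and
#' maximum end position of a set of transitively overlapping exons.
#' Book-ended exons (sharing a boundary but no base) are NOT merged. The
#' result is sorted and pairwise disjoint, and every exon belongs to exactly
#' one meta-exon.
#'
#' @param gene a [gene_model].
#' @param transcripts optional transcript-id subset (e.g. after isoform
#'   selection).
#' @return data.frame with columns `chrom`, `start`, `end`, `n_members`
#'   (number of member exon records).
#' @export
build_meta_exons <- function(gene, transcripts = NULL) {
  ex <- gene_exons(gene, transcripts)
  if (nrow(ex) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_members = integer()))
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(ir, red)
  data.frame(chrom = gene$chrom,
             start = IRanges::start(red) - 1L,
             end = IRanges::end(red),
             n_members = as.integer(table(factor(S4Vectors::subjectHits(hit),
                                                 levels = seq_along(red)))))
}

#' Annotate transcripts of other genes overlapping a gene locus
#'
#' Every transcript of another gene whose span intersects the query gene's
#' span yields one annotation: orientation `sense`/`antisense` by strand
#' comparison, and `overlap_kind = "exonic"` iff any exon of the other
#' transcript intersects any exon of the query gene (else `"non_exonic"`).
#'
#' @param gene query [gene_model].
#' @param annotation list of [gene_model]s (the query gene itself is
#'   skipped by id).
#' @return data.frame with columns `other_gene_id`, `other_transcript_id`,
#'   `orientation`, `overlap_kind`, `start`, `end` (span of the overlapping
#'   transcript intersected with the query span).
#' @export
annotate_overlaps <- function(gene, annotation) {
  q_ex <- gene_exons(gene)
  rows <- list()
  for (other in annotation) {
    if (other$gene_id == gene$gene_id || other$chrom != gene$chrom) next
    for (tx in other$transcripts) {
      ts <- min(tx$exons$start); te <- max(tx$exons$end)
      if (ts >= gene$end || te <= gene$start) next
      exonic <- any(outer(tx$exons$start, q_ex$end, `<`) &
                    outer(tx$exons$end, q_ex$start, `>`))
      rows[[length(rows) + 1L]] <- data.frame(
        other_gene_id = other$gene_id, other_transcript_id = tx$id,
        orientation = if (other$strand == gene$strand) "sense" else "antisense",
        overlap_kind = if (exonic) "exonic" else "non_exonic",
        start = max(ts, gene$start), end = min(te, gene$end),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(other_gene_id = character(),
                      other_transcript_id = character(),
                      orientation = character(), overlap_kind = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

#' Represent a novel junction as an incomplete isoform
#'
#' An unannotated splice junction inside a known gene is represented by a
#' synthetic two-exon transcript reduced to the putative exon end and exon
#' start surrounding the junction: one exon of length `flank` ending at the
#' junction donor and one starting at the acceptor (clipped to the gene
#' span). The transcript is flagged `is_incomplete`.
#'
#' @param gene a [gene_model].
#' @param donor_end,acceptor_start junction intron coordinates (0-based;
#'   `donor_end` < `acceptor_start`).
#' @param flank stub exon length in bases (default 50).
#' @param id transcript id for the synthetic isoform.
#' @return A transcript list (as stored in `gene$transcripts`) with
#'   `is_incomplete = TRUE`.
#' @export
make_incomplete_isoform <- function(gene, donor_end, acceptor_start,
                                    flank = 50L, id = NULL) {
  if (donor_end >= acceptor_start)
    stop("junction must have donor_end < acceptor_start")
  if (donor_end <= gene$start || acceptor_start >= gene$end)
    stop("junction (", donor_end, ",", acceptor_start,
         ") lies outside gene span [", gene$start, ",", gene$end, ")")
  intr <- gene_introns(gene)
  if (any(intr$donor_end == donor_end & intr$acceptor_start == acceptor_start))
    stop("junction (", donor_end, ",", acceptor_start, ") is already annotated")
  if (is.null(id))
    id <- sprintf("%s.novel.%d.%d", gene$gene_id, donor_end, acceptor_start)
  up <- data.frame(start = max(gene$start, donor_end - flank), end = donor_end)
  dn <- data.frame(start = acceptor_start,
                   end = min(gene$end, acceptor_start + flank))
  list(id = id, exons = rbind(up, dn), is_incomplete = TRUE)
}

#' Add a transcript to a gene model
#'
#' @param gene a [gene_model].
#' @param tx a transcript list (e.g. from [make_incomplete_isoform()]).
#' @return The updated [gene_model].
#' @export
add_transcript <- function(gene, tx) {
  gene_model(gene$gene_id, gene$chrom, gene$strand,
             c(gene$transcripts, list(tx)))
}
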