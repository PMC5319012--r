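# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# Transitive merge of exons sharing at least one base, by repeated
# pairwise merging (book-ended intervals share no base and stay apart).
bf_meta_exons <- function(starts, ends) {
  iv <- unique(data.frame(start = starts, end = ends))
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(iv))) {
      for (j in seq_len(nrow(iv))) {
        if (i >= j) next
        if (iv$start[i] < iv$end[j] && iv$end[i] > iv$start[j]) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv <- iv[order(iv$start), ]
  rownames(iv) <- NULL
  iv
}

# Linear scan for fully contained introns.
bf_query <- function(junctions, chrom, start, end) {
  hits <- integer()
  for (i in seq_len(nrow(junctions))) {
    if (junctions$chrom[i] == chrom &&
        junctions$donor_end[i] >= start &&
        junctions$acceptor_start[i] <= end)
      hits <- c(hits, i)
  }
  hits
}

# All inclusion/exclusion combinations by explicit double loop.
bf_pairs <- function(junctions, meta_start, meta_end) {
  out <- NULL
  for (i in seq_len(nrow(junctions))) {
    incl_ok <- junctions$acceptor_start[i] == meta_start ||
      junctions$donor_end[i] == meta_end
    if (!incl_ok) next
    for (j in seq_len(nrow(junctions))) {
      span_ok <- junctions$donor_end[j] <= meta_start &&
        junctions$acceptor_start[j] >= meta_end &&
        !(junctions$donor_end[j] == meta_start &&
            junctions$acceptor_start[j] == meta_end)
      if (span_ok) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Exhaustive argmax with the documented tie-break chain.
bf_best <- function(delta, total, incl_d, incl_a, excl_d, excl_a) {
  delta[is.na(delta)] <- -Inf
  best <- 1L
  for (k in seq_along(delta)[-1L]) {
    better <- FALSE
    if (delta[k] > delta[best]) better <- TRUE
    else if (delta[k] == delta[best]) {
      if (total[k] > total[best]) better <- TRUE
      else if (total[k] == total[best]) {
        a <- c(incl_d[k], incl_a[k], excl_d[k], excl_a[k])
        b <- c(incl_d[best], incl_a[best], excl_d[best], excl_a[best])
        d <- which(a != b)
        if (length(d) && a[d[1L]] < b[d[1L]]) better <- TRUE
      }
    }
    if (better) best <- k
  }
  best
}

# Independent event-type rule table.
bf_classify <- function(id, ia, ed, ea, metas, target, strand) {
  inside <- which(metas$start >= ed & metas$end <= ea)
  if ((id == ed || ia == ea) && length(inside) == 1L && inside == target)
    return("exon_skipping")
  same_left <- id == ed; same_right <- ia == ea
  if (same_left == same_right) return("other")
  left_varies <- same_right
  if (strand == "+") {
    if (left_varies) "alt_donor" else "alt_acceptor"
  } else {
    if (left_varies) "alt_acceptor" else "alt_donor"
  }
}

# All-pairs interval check for overlap annotations.
bf_overlaps <- function(gene, others) {
  out <- NULL
  qex <- gene_exons(gene)
  for (g in others) {
    if (g$gene_id == gene$gene_id || g$chrom != gene$chrom) next
    for (tx in g$transcripts) {
      s <- min(tx$exons$start); e <- max(tx$exons$end)
      if (!(s < gene$end && e > gene$start)) next
      exonic <- FALSE
      for (i in seq_len(nrow(tx$exons)))
        for (k in seq_len(nrow(qex)))
          if (tx$exons$start[i] < qex$end[k] && tx$exons$end[i] > qex$start[k])
            exonic <- TRUE
      out <- rbind(out, data.frame(
        tx = tx$id,
        orientation = if (g$strand == gene$strand) "sense" else "antisense",
        kind = if (exonic) "exonic" else "non_exonic",
        stringsAsFactors = FALSE))
    }
  }
  out
}

# Small random gene with irregular exon structure, for property tests.
random_gene <- function(n_tx = 3L, max_exons = 6L, chrom = "chrR") {
  txs <- lapply(seq_len(n_tx), function(i) {
    n <- sample(2:max_exons, 1L)
    starts <- sort(sample(seq(0L, 5000L, by = 10L), n))
    lens <- sample(20:120, n, replace = TRUE)
    ex <- data.frame(start = starts, end = starts + lens)
    # enforce intron length >= 1 by pushing starts right when needed
    for (k in seq_len(n)[-1L])
      if (ex$start[k] <= ex$end[k - 1L]) {
        shift <- ex$end[k - 1L] + sample(1:50, 1L) - ex$start[k]
        ex$start[k] <- ex$start[k] + shift
        ex$end[k] <- ex$end[k] + shift
      }
    list(id = sprintf("T%d", i), exons = ex)
  })
  gene_model("RANDGENE", chrom, sample(c("+", "-"), 1L), txs)
}

# Junction table built directly from per-sample data.frames.
make_table <- function(per_sample, annotation = NULL)
  merge_junction_tables(per_sample, annotation)

jdf <- function(chrom, d, a, count)
  data.frame(chrom = rep_len(chrom, length(d)), donor_end = d,
             acceptor_start = a, strand = rep_len("*", length(d)),
             count = count, stringsAsFactors = FALSE)
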