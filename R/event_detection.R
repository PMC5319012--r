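## Core caller: isoform pre-selection, inclusion/exclusion junction-pair PSI
## scoring, per-nucleotide coverage-ratio testing, candidate assembly.

#' Detection thresholds and options
#'
#' @param p_threshold maximum p-value for either test (default 0.05).
#' @param min_delta_psi minimum absolute between-condition PSI difference
#'   (default 0.1; changes below ~0.1-0.15 are weak candidates).
#' @param min_delta_ratio minimum absolute coverage-ratio difference
#'   between the target exon group and the background groups (default 0.1).
#' @param min_depth minimum mean adjusted per-base coverage for a base to
#'   count as covered during isoform selection (default 5).
#' @param min_frac minimum fraction of covered bases per exon for an
#'   isoform to be retained (default 0.7).
#' @param raw_junction_psi if `TRUE`, PSI is computed from raw rather than
#'   size-factor-adjusted junction counts.
#' @return list of options consumed by [detect_events()].
#' @export
detection_defaults <- function(p_threshold = 0.05, min_delta_psi = 0.1,
                               min_delta_ratio = 0.1, min_depth = 5,
                               min_frac = 0.7, raw_junction_psi = FALSE) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            min_delta_psi >= 0, min_delta_psi <= 1,
            min_delta_ratio >= 0, min_delta_ratio <= 1,
            min_depth >= 0, min_frac >= 0, min_frac <= 1)
  list(p_threshold = p_threshold, min_delta_psi = min_delta_psi,
       min_delta_ratio = min_delta_ratio, min_depth = min_depth,
       min_frac = min_frac, raw_junction_psi = isTRUE(raw_junction_psi))
}

## Welch two-sample t-test p-value with degenerate-variance guards: equal
## constant groups are uninformative (p = 1), distinct constant groups are
## maximally separated (p = 0).
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::var(x) + stats::var(y) < 1e-24)
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
}

#' Automated isoform pre-selection
#'
#' Discards isoforms containing exons with insufficient coverage: a
#' transcript is retained iff every one of its exons has a covered fraction
#' (share of bases whose mean adjusted coverage within a condition is at
#' least `min_depth`) of at least `min_frac` in at least one condition. If
#' no transcript qualifies, the best-scoring one (largest minimum per-exon
#' covered fraction) is retained so the gene is never left empty.
#'
#' @param gene a [gene_model].
#' @param coverage a `coverage_set` over the gene span, already adjusted by
#'   size factors.
#' @param min_depth,min_frac see [detection_defaults()].
#' @return character vector of retained transcript ids.
#' @export
select_isoforms <- function(gene, coverage, min_depth = 5, min_frac = 0.7) {
  conds <- unique(coverage$conditions)
  cond_mean <- vapply(conds, function(cc)
    rowMeans(coverage$mat[, coverage$conditions == cc, drop = FALSE]),
    numeric(nrow(coverage$mat)))
  covered <- cond_mean >= min_depth       # base x condition
  score <- vapply(gene$transcripts, function(tx) {
    fr <- vapply(seq_len(nrow(tx$exons)), function(i) {
      rows <- (tx$exons$start[i] - coverage$start + 1L):
              (tx$exons$end[i] - coverage$start)
      max(colMeans(covered[rows, , drop = FALSE]))
    }, numeric(1L))
    min(fr)                               # worst exon, best condition
  }, numeric(1L))
  keep <- names(score)[score >= min_frac]
  if (length(keep) == 0L) keep <- names(score)[which.max(score)]
  keep
}

#' Enumerate inclusion/exclusion junction pairs for a meta-exon
#'
#' All combinations of one inclusion junction (intron abutting the
#' meta-exon: `acceptor_start == start` or `donor_end == end`) and one
#' exclusion junction (intron containing the whole meta-exon). A pair is
#' flagged `uses_novel` when either member is absent from the annotation.
#'
#' @param table a `junction_table` (typically restricted to the gene span).
#' @param meta one-row data.frame with `start`, `end` (a meta-exon).
#' @return data.frame with columns `incl`, `excl` (row indices into
#'   `table$junctions`) and `uses_novel`.
#' @export
enumerate_pairs <- function(table, meta) {
  j <- table$junctions
  incl <- which(j$acceptor_start == meta$start | j$donor_end == meta$end)
  excl <- which(j$donor_end <= meta$start & j$acceptor_start >= meta$end &
                  !(j$donor_end == meta$start & j$acceptor_start == meta$end))
  if (length(incl) == 0L || length(excl) == 0L)
    return(data.frame(incl = integer(), excl = integer(),
                      uses_novel = logical()))
  out <- expand.grid(incl = incl, excl = excl, KEEP.OUT.ATTRS = FALSE)
  out$uses_novel <- !j$known[out$incl] | !j$known[out$excl]
  out
}

#' PSI score and test for one junction pair
#'
#' Per-sample PSI is `incl / (incl + excl)` on size-factor-adjusted counts
#' (undefined when the denominator is 0; undefined samples are excluded
#' from means and the test). The two condition groups are compared with a
#' Welch t-test on the per-sample PSI values; the p-value is undefined with
#' fewer than 2 defined samples in either condition.
#'
#' @param table a `junction_table`.
#' @param incl,excl row indices of the inclusion and exclusion junction.
#' @param size_factors a `size_factors` object (or numeric vector), one per
#'   sample.
#' @param conditions per-sample condition labels.
#' @param cond_a,cond_b the two condition labels compared.
#' @param raw if `TRUE`, use raw counts (skip size-factor adjustment).
#' @return list with `psi` (named per-sample vector), `mean_a`, `mean_b`,
#'   `delta` (signed `mean_a - mean_b`), `p`, and `total` (total adjusted
#'   count over both junctions, used for tie-breaking).
#' @export
score_pair <- function(table, incl, excl, size_factors, conditions,
                       cond_a, cond_b, raw = FALSE) {
  ci <- table$counts[incl, ]
  ce <- table$counts[excl, ]
  if (!raw) {
    ci <- adjust(ci, size_factors)
    ce <- adjust(ce, size_factors)
  }
  tot <- ci + ce
  psi <- ifelse(tot > 0, ci / tot, NA_real_)
  names(psi) <- table$samples
  a <- psi[conditions == cond_a]; a <- a[!is.na(a)]
  b <- psi[conditions == cond_b]; b <- b[!is.na(b)]
  mean_a <- if (length(a)) mean(a) else NA_real_
  mean_b <- if (length(b)) mean(b) else NA_real_
  list(psi = psi, mean_a = mean_a, mean_b = mean_b,
       delta = mean_a - mean_b, p = welch_p(a, b), total = sum(tot))
}

#' Select the junction pair with the largest PSI difference
#'
#' Ties are broken by larger total adjusted count, then lexicographically
#' smallest junction coordinates. If the winning pair involves an
#' unannotated junction, the best pair among known-only junctions is
#' additionally reported.
#'
#' @param pairs data.frame from [enumerate_pairs()].
#' @param scores list of [score_pair()] results, parallel to `pairs` rows.
#' @param table the `junction_table` the indices refer to.
#' @return list with `best` (row index into `pairs`) and `best_known`
#'   (row index of the best known-only pair when `best` uses a novel
#'   junction and a known-only pair exists, else `NA`).
#' @export
best_pair <- function(pairs, scores, table) {
  stopifnot(nrow(pairs) >= 1L, length(scores) == nrow(pairs))
  j <- table$junctions
  delta <- vapply(scores, function(s) abs(s$delta), numeric(1L))
  delta[is.na(delta)] <- -Inf
  total <- vapply(scores, `[[`, numeric(1L), "total")
  ord <- order(-delta, -total, j$donor_end[pairs$incl],
               j$acceptor_start[pairs$incl], j$donor_end[pairs$excl],
               j$acceptor_start[pairs$excl])
  best <- ord[1L]
  best_known <- NA_integer_
  if (pairs$uses_novel[best]) {
    known <- ord[!pairs$uses_novel[ord]]
    if (length(known)) best_known <- known[1L]
  }
  list(best = best, best_known = best_known)
}

#' Per-nucleotide coverage-ratio test for one exon group
#'
#' At each base p, the coverage ratio is
#' `r(p) = m_A(p) / (m_A(p) + m_B(p))` with `m_c` the mean adjusted
#' coverage of condition c (undefined where the denominator is 0). The
#' defined ratios of each nucleotide of the query exon group are tested
#' (Welch t-test) against the per-group mean ratios of the remaining exon
#' groups of the gene. The result is flagged untestable with fewer than 2
#' remaining groups or fewer than 2 defined target bases.
#'
#' @param coverage a `coverage_set`, adjusted by size factors.
#' @param groups data.frame of exon groups (`start`, `end`), e.g. meta-exons
#'   of the selected isoforms.
#' @param target row index (or indices) in `groups` of the query group.
#' @param cond_a,cond_b the two condition labels compared.
#' @return list with `ratio` (per-base vector over the span), `target_mean`,
#'   `background_mean`, `delta` (signed), `p`, `testable`.
#' @export
ratio_test <- function(coverage, groups, target, cond_a, cond_b) {
  stopifnot(all(c(cond_a, cond_b) %in% coverage$conditions))
  mA <- rowMeans(coverage$mat[, coverage$conditions == cond_a, drop = FALSE])
  mB <- rowMeans(coverage$mat[, coverage$conditions == cond_b, drop = FALSE])
  denom <- mA + mB
  r <- ifelse(denom > 0, mA / denom, NA_real_)
  base_rows <- function(i)
    (groups$start[i] - coverage$start + 1L):(groups$end[i] - coverage$start)
  s1 <- r[unlist(lapply(target, base_rows))]
  s1 <- s1[!is.na(s1)]
  rest <- setdiff(seq_len(nrow(groups)), target)
  s2 <- vapply(rest, function(i) mean(r[base_rows(i)], na.rm = TRUE),
               numeric(1L))
  s2 <- s2[is.finite(s2)]
  if (length(s1) < 2L || length(s2) < 2L)
    return(list(ratio = r, target_mean = NA_real_, background_mean = NA_real_,
                delta = NA_real_, p = NA_real_, testable = FALSE))
  list(ratio = r, target_mean = mean(s1), background_mean = mean(s2),
       delta = mean(s1) - mean(s2), p = welch_p(s1, s2), testable = TRUE)
}

#' Classify the event type of a junction pair
#'
#' `exon_skipping`: the two introns share their outer anchor coordinate and
#' the exclusion intron skips exactly the target meta-exon. `alt_donor` /
#' `alt_acceptor`: the introns share one splice site and differ at the
#' other; which label applies follows the gene strand (on `+`, the left
#' intron edge is the donor). Everything else is `other`.
#'
#' @param incl_donor,incl_acceptor inclusion intron coordinates.
#' @param excl_donor,excl_acceptor exclusion intron coordinates.
#' @param meta_exons data.frame of the gene's meta-exons.
#' @param target row index of the target meta-exon.
#' @param strand gene strand.
#' @return one of `"exon_skipping"`, `"alt_donor"`, `"alt_acceptor"`,
#'   `"other"`.
#' @export
classify_event <- function(incl_donor, incl_acceptor, excl_donor,
                           excl_acceptor, meta_exons, target, strand) {
  share_left <- incl_donor == excl_donor
  share_right <- incl_acceptor == excl_acceptor
  contained <- which(meta_exons$start >= excl_donor &
                       meta_exons$end <= excl_acceptor)
  if ((share_left || share_right) && length(contained) == 1L &&
      contained == target)
    return("exon_skipping")
  if (xor(share_left, share_right)) {
    varies_left <- share_right                 # differing coordinate side
    if (strand == "+")
      return(if (varies_left) "alt_donor" else "alt_acceptor")
    return(if (varies_left) "alt_acceptor" else "alt_donor")
  }
  "other"
}

#' Detect alternative splicing events in one gene
#'
#' For every meta-exon and every unordered pair of conditions, runs the
#' junction-pair PSI path ([enumerate_pairs()], [score_pair()],
#' [best_pair()]) and the coverage-ratio path ([ratio_test()] over the exon
#' groups of the automatically selected isoforms). A candidate is emitted
#' when either test passes (`p <= p_threshold` and absolute difference at
#' least the corresponding `min_delta`); its `support_class` records which.
#' Exon-skipping candidates supported by both tests are flagged
#' `highlight`. The list is sorted by minimum p-value; a
#' Benjamini-Hochberg-adjusted column is included for reference but not
#' used for filtering.
#'
#' @param gene a [gene_model].
#' @param table a `junction_table` over the gene span (raw counts).
#' @param coverage a `coverage_set` over the gene span (raw).
#' @param size_factors a `size_factors` object, one factor per sample.
#' @param config options from [detection_defaults()].
#' @return data.frame of candidates (one row per meta-exon x condition
#'   pair that passed), with per-sample `psi_*` columns; zero rows when
#'   nothing passes.
#' @export
detect_events <- function(gene, table, coverage, size_factors,
                          config = detection_defaults()) {
  stopifnot(inherits(gene, "gene_model"),
            identical(table$samples, coverage$samples))
  conds <- sort(unique(coverage$conditions))
  if (length(conds) < 2L)
    stop("detection requires at least two conditions")
  no_junctions <- nrow(table$junctions) == 0L  # no evidence, no events
  cov_adj <- coverage
  cov_adj$mat <- adjust(coverage$mat, size_factors)
  selected <- select_isoforms(gene, cov_adj, config$min_depth,
                              config$min_frac)
  groups <- build_meta_exons(gene, selected)
  metas <- build_meta_exons(gene)
  psi_cols <- paste0("psi_", table$samples)
  rows <- list()
  for (ca_i in seq_len(length(conds) - 1L)) for (cb_i in (ca_i + 1L):length(conds)) {
    if (no_junctions) break
    ca <- conds[ca_i]; cb <- conds[cb_i]
    for (mi in seq_len(nrow(metas))) {
      prs <- enumerate_pairs(table, metas[mi, ])
      psi_p <- NA_real_; psi_delta <- NA_real_
      mean_a <- NA_real_; mean_b <- NA_real_
      psi <- setNames(rep(NA_real_, length(table$samples)), table$samples)
      pair_str <- known_str <- NA_character_
      uses_novel <- FALSE
      etype <- "other"
      if (nrow(prs) > 0L) {
        scores <- lapply(seq_len(nrow(prs)), function(k)
          score_pair(table, prs$incl[k], prs$excl[k], size_factors,
                     coverage$conditions, ca, cb,
                     raw = config$raw_junction_psi))
        bp <- best_pair(prs, scores, table)
        sc <- scores[[bp$best]]
        psi <- sc$psi; mean_a <- sc$mean_a; mean_b <- sc$mean_b
        psi_delta <- sc$delta; psi_p <- sc$p
        uses_novel <- prs$uses_novel[bp$best]
        jfmt <- function(k) sprintf("%d-%d", table$junctions$donor_end[k],
                                    table$junctions$acceptor_start[k])
        pair_str <- paste(jfmt(prs$incl[bp$best]), jfmt(prs$excl[bp$best]),
                          sep = "|")
        if (!is.na(bp$best_known))
          known_str <- paste(jfmt(prs$incl[bp$best_known]),
                             jfmt(prs$excl[bp$best_known]), sep = "|")
        etype <- classify_event(
          table$junctions$donor_end[prs$incl[bp$best]],
          table$junctions$acceptor_start[prs$incl[bp$best]],
          table$junctions$donor_end[prs$excl[bp$best]],
          table$junctions$acceptor_start[prs$excl[bp$best]],
          metas, mi, gene$strand)
      }
      tg <- which(groups$start < metas$end[mi] & groups$end > metas$start[mi])
      rt <- if (length(tg) > 0L)
        ratio_test(cov_adj, groups, tg, ca, cb)
      else list(delta = NA_real_, p = NA_real_, testable = FALSE)
      psi_pass <- !is.na(psi_p) && psi_p <= config$p_threshold &&
        !is.na(psi_delta) && abs(psi_delta) >= config$min_delta_psi
      ratio_pass <- rt$testable && !is.na(rt$p) &&
        rt$p <= config$p_threshold && abs(rt$delta) >= config$min_delta_ratio
      if (!psi_pass && !ratio_pass) next
      support <- if (psi_pass && ratio_pass) "both"
                 else if (psi_pass) "psi_only" else "ratio_only"
      row <- data.frame(
        gene = gene$gene_id, chrom = gene$chrom,
        meta_exon_start = metas$start[mi], meta_exon_end = metas$end[mi],
        event_type = etype, condition_a = ca, condition_b = cb,
        junction_pair = pair_str, known_only_pair = known_str,
        uses_novel = uses_novel,
        mean_psi_a = mean_a, mean_psi_b = mean_b,
        delta_psi = psi_delta, psi_pvalue = psi_p,
        delta_ratio = rt$delta, ratio_pvalue = rt$p,
        support_class = support,
        highlight = etype == "exon_skipping" && support == "both",
        stringsAsFactors = FALSE)
      row[psi_cols] <- as.list(psi)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(), chrom = character(), meta_exon_start = integer(),
      meta_exon_end = integer(), event_type = character(),
      condition_a = character(), condition_b = character(),
      junction_pair = character(), known_only_pair = character(),
      uses_novel = logical(), mean_psi_a = numeric(), mean_psi_b = numeric(),
      delta_psi = numeric(), psi_pvalue = numeric(), delta_ratio = numeric(),
      ratio_pvalue = numeric(), support_class = character(),
      highlight = logical(), stringsAsFactors = FALSE)
    out[psi_cols] <- lapply(psi_cols, function(x) numeric())
  }
  out$min_pvalue <- pmin(out$psi_pvalue, out$ratio_pvalue, na.rm = TRUE)
  out <- out[order(out$min_pvalue, out$meta_exon_start), , drop = FALSE]
  out$psi_pvalue_bh <- p.adjust(out$psi_pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a candidate table as TSV
#'
#' @param results data.frame from [detect_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
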