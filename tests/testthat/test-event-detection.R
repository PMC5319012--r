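# A compact cassette-exon fixture used across several blocks.
cassette_sim <- function(seed = 1, ...) simulate_counts(sim_scenario(seed = seed, ...))

test_that("isoform selection keeps covered isoforms and discards dead ones", {
  sim <- cassette_sim(3, psi = c(A = 0, B = 0))   # cassette never included
  cov <- sim$coverage
  sel <- select_isoforms(sim$gene, cov)
  expect_equal(sel, "SIMGENE.skip")
  sim2 <- cassette_sim(3, psi = c(A = 1, B = 1))  # uniformly covered
  expect_setequal(select_isoforms(sim2$gene, sim2$coverage),
                  c("SIMGENE.incl", "SIMGENE.skip"))
  # even a gene where nothing passes keeps its best transcript
  cov0 <- cov; cov0$mat[] <- 0
  expect_length(select_isoforms(sim$gene, cov0), 1L)
})

test_that("unexpressed isoforms do not change junction-level detection", {
  sim <- cassette_sim(17, psi = c(A = 0.01, B = 0.01))
  sel <- select_isoforms(sim$gene, sim$coverage)
  expect_false("SIMGENE.incl" %in% sel)
  sf <- user_size_factors(setNames(rep(1, 6L), sim$coverage$samples))
  res <- detect_events(sim$gene, sim$table, sim$coverage, sf)
  # null PSI difference: junction path stays quiet regardless of selection
  expect_true(all(res$support_class != "psi_only"))
})

test_that("pair enumeration matches the brute-force double loop", {
  # cassette exon with 2 inclusion + 1 exclusion junctions -> 2 pairs
  tab <- make_table(list(s = jdf("c", c(100L, 300L, 100L), c(200L, 500L, 500L),
                                 c(5, 5, 5))))
  meta <- data.frame(start = 200L, end = 300L)
  prs <- enumerate_pairs(tab, meta)
  expect_equal(nrow(prs), 2L)
  # an exon with no spanning junction yields nothing
  expect_equal(nrow(enumerate_pairs(tab, data.frame(start = 600L, end = 700L))),
               0L)
  set.seed(23)
  for (i in 1:50) {
    n <- sample(3:12, 1L)
    d <- sample(seq(0L, 900L, 10L), n)
    tabr <- make_table(list(s = jdf("c", d, d + sample(20:600, n, TRUE),
                                    sample(1:9, n, TRUE))))
    ms <- sample(seq(0L, 900L, 10L), 1L)
    metar <- data.frame(start = ms, end = ms + sample(c(20L, 50L, 100L), 1L))
    got <- enumerate_pairs(tabr, metar)
    want <- bf_pairs(tabr$junctions, metar$start, metar$end)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_setequal(paste(got$incl, got$excl),
                      paste(want[, 1L], want[, 2L]))
    }
  }
})

test_that("PSI scoring is symmetric, bounded, and role-swap antisymmetric", {
  tab <- make_table(list(a1 = jdf("c", c(100L, 100L), c(200L, 500L), c(50, 50)),
                         a2 = jdf("c", c(100L, 100L), c(200L, 500L), c(50, 50)),
                         b1 = jdf("c", c(100L, 100L), c(200L, 500L), c(50, 50)),
                         b2 = jdf("c", c(100L, 100L), c(200L, 500L), c(50, 50))))
  conds <- c("A", "A", "B", "B")
  sf <- rep(1, 4L)
  s <- score_pair(tab, 1L, 2L, sf, conds, "A", "B")
  expect_equal(unname(s$psi), rep(0.5, 4L))
  expect_equal(s$delta, 0)
  expect_equal(s$p, 1)
  # zero inclusion everywhere
  tab0 <- make_table(list(a1 = jdf("c", 100L, 500L, 10),
                          a2 = jdf("c", 100L, 500L, 12),
                          b1 = jdf("c", 100L, 500L, 9),
                          b2 = jdf("c", c(100L, 100L), c(200L, 500L), c(8, 8))))
  i_in <- which(tab0$junctions$acceptor_start == 200L)
  i_ex <- which(tab0$junctions$acceptor_start == 500L)
  s0 <- score_pair(tab0, i_in, i_ex, sf, conds, "A", "B")
  expect_equal(unname(s0$psi[1:3]), c(0, 0, 0))
  # swapping inclusion and exclusion maps PSI to 1 - PSI
  set.seed(99)
  tabr <- make_table(list(a1 = jdf("c", c(100L, 100L), c(200L, 500L), rpois(2, 40)),
                          a2 = jdf("c", c(100L, 100L), c(200L, 500L), rpois(2, 40)),
                          b1 = jdf("c", c(100L, 100L), c(200L, 500L), rpois(2, 40)),
                          b2 = jdf("c", c(100L, 100L), c(200L, 500L), rpois(2, 40))))
  fwd <- score_pair(tabr, 1L, 2L, sf, conds, "A", "B")
  rev <- score_pair(tabr, 2L, 1L, sf, conds, "A", "B")
  expect_equal(rev$psi, 1 - fwd$psi)
  expect_equal(rev$delta, -fwd$delta)
  expect_equal(rev$p, fwd$p)
  # condition-label swap negates the signed delta, p unchanged
  swp <- score_pair(tabr, 1L, 2L, sf, conds, "B", "A")
  expect_equal(swp$delta, -fwd$delta)
  expect_equal(swp$p, fwd$p)
})

test_that("estimated delta PSI tracks the simulated truth", {
  set.seed(12)
  deltas <- vapply(1:60, function(i) {
    sim <- cassette_sim(sample.int(1e6, 1L))
    sf <- user_size_factors(setNames(rep(1, 6L), sim$coverage$samples))
    res <- detect_events(sim$gene, sim$table, sim$coverage, sf)
    res$delta_psi[1L]
  }, numeric(1L))
  expect_equal(mean(deltas), 0.5, tolerance = 0.05)
})

test_that("best pair maximizes delta with the documented tie-break", {
  tab <- make_table(list(s = jdf("c", c(100L, 100L, 50L), c(200L, 500L, 500L),
                                 c(5, 5, 5))))
  pairs <- data.frame(incl = c(1L, 1L), excl = c(2L, 3L),
                      uses_novel = c(FALSE, FALSE))
  scores <- list(list(delta = 0.4, total = 10),
                 list(delta = 0.1, total = 99))
  expect_equal(best_pair(pairs, scores, tab)$best, 1L)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(2:8, 1L)
    d <- sample(seq(0L, 300L, 10L), n, replace = FALSE)
    tabr <- make_table(list(s = jdf("c", d, d + sample(20:400, n, TRUE),
                                    sample(1:9, n, TRUE))))
    npair <- sample(2:6, 1L)
    prs <- data.frame(incl = sample(n, npair, TRUE),
                      excl = sample(n, npair, TRUE),
                      uses_novel = sample(c(TRUE, FALSE), npair, TRUE))
    sc <- lapply(seq_len(npair), function(k)
      list(delta = sample(c(NA, 0, 0.1, 0.1, 0.3), 1L)[[1L]],
           total = sample(c(10, 10, 20), 1L)))
    got <- best_pair(prs, sc, tabr)
    j <- tabr$junctions
    want <- bf_best(vapply(sc, function(s) abs(s$delta), numeric(1L)),
                    vapply(sc, `[[`, numeric(1L), "total"),
                    j$donor_end[prs$incl], j$acceptor_start[prs$incl],
                    j$donor_end[prs$excl], j$acceptor_start[prs$excl])
    expect_equal(got$best, want)
    if (prs$uses_novel[got$best] && any(!prs$uses_novel)) {
      keep <- which(!prs$uses_novel)
      wk <- keep[bf_best(
        vapply(sc[keep], function(s) abs(s$delta), numeric(1L)),
        vapply(sc[keep], `[[`, numeric(1L), "total"),
        j$donor_end[prs$incl[keep]], j$acceptor_start[prs$incl[keep]],
        j$donor_end[prs$excl[keep]], j$acceptor_start[prs$excl[keep]])]
      expect_equal(got$best_known, wk)
    } else {
      expect_true(is.na(got$best_known))
    }
  }
})

test_that("ratio test is symmetric under equal coverage and sharp in the limit", {
  sim <- cassette_sim(41, psi = c(A = 0.5, B = 0.5), noise = "none")
  groups <- build_meta_exons(sim$gene)
  rt <- ratio_test(sim$coverage, groups, 3L, "A", "B")
  expect_true(rt$testable)
  expect_equal(rt$delta, 0)
  expect_equal(rt$p, 1)
  expect_true(all(rt$ratio == 0.5, na.rm = TRUE))
  # target exon expressed only in condition A -> target ratio 1, background 0.5
  lim <- cassette_sim(41, psi = c(A = 1, B = 0), noise = "none")
  rt2 <- ratio_test(lim$coverage, groups, 3L, "A", "B")
  expect_equal(rt2$target_mean, 1)
  expect_equal(rt2$background_mean, 0.5)
  # fewer than two background groups is untestable
  expect_false(ratio_test(sim$coverage, groups[2:3, ], 2L, "A", "B")$testable)
})

test_that("event classification matches the brute-force rule table", {
  metas <- data.frame(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L))
  # canonical cassette trio
  expect_equal(classify_event(100L, 200L, 100L, 400L, metas, 2L, "+"),
               "exon_skipping")
  # shared acceptor, differing donors
  expect_equal(classify_event(120L, 400L, 100L, 400L, metas, 3L, "+"),
               "alt_donor")
  expect_equal(classify_event(120L, 400L, 100L, 400L, metas, 3L, "-"),
               "alt_acceptor")
  set.seed(61)
  for (i in 1:200) {
    n <- sample(3:6, 1L)
    s <- sort(sample(seq(0L, 2000L, 100L), n))
    mr <- data.frame(start = s, end = s + 50L)
    tgt <- sample(n, 1L)
    coords <- sample(c(mr$start, mr$end, sample(0:2000, 4L)), 4L, TRUE)
    id <- min(coords[1:2]); ia <- max(coords[1:2]) + 1L
    ed <- min(coords[3:4]); ea <- max(coords[3:4]) + 1L
    strand <- sample(c("+", "-"), 1L)
    expect_equal(classify_event(id, ia, ed, ea, mr, tgt, strand),
                 bf_classify(id, ia, ed, ea, mr, tgt, strand))
  }
})

test_that("detection finds a simulated cassette exon with both supports", {
  sim <- cassette_sim(7)
  sf <- user_size_factors(setNames(rep(1, 6L), sim$coverage$samples))
  res <- detect_events(sim$gene, sim$table, sim$coverage, sf)
  expect_equal(nrow(res), 1L)
  expect_equal(res$meta_exon_start, sim$truth$meta_exon_start)
  expect_equal(res$meta_exon_end, sim$truth$meta_exon_end)
  expect_equal(res$event_type, "exon_skipping")
  expect_equal(res$support_class, "both")
  expect_true(res$highlight)
  # per-sample PSI columns are present and in range
  psis <- unlist(res[paste0("psi_", sim$coverage$samples)])
  expect_true(all(psis >= 0 & psis <= 1))
  # no junctions at all -> empty result
  tab0 <- make_table(list(s = jdf("c", integer(), integer(), numeric())))
  tab0$samples <- sim$table$samples
  tab0$counts <- matrix(0, 0L, 6L, dimnames = list(NULL, sim$table$samples))
  res0 <- detect_events(sim$gene, tab0, sim$coverage, sf)
  expect_equal(nrow(res0), 0L)
})

test_that("detection is deterministic and size-factor invariant", {
  sim <- cassette_sim(19)
  sf1 <- user_size_factors(setNames(rep(1, 6L), sim$coverage$samples))
  r1 <- detect_events(sim$gene, sim$table, sim$coverage, sf1)
  r2 <- detect_events(sim$gene, sim$table, sim$coverage, sf1)
  expect_identical(r1, r2)
  # scaling every sample by its factor and passing those factors is a no-op
  f <- c(0.5, 1, 2, 0.8, 1.6, 1.25)
  simf <- sim
  simf$table$counts <- sweep(sim$table$counts, 2L, f, `*`)
  simf$coverage$mat <- sweep(sim$coverage$mat, 2L, f, `*`)
  rf <- detect_events(simf$gene, simf$table, simf$coverage,
                      user_size_factors(setNames(f, sim$coverage$samples)))
  expect_equal(rf, r1)
  # swapping condition labels negates signed deltas, keeps p-values
  simswap <- sim
  simswap$coverage$conditions <- chartr("AB", "BA", sim$coverage$conditions)
  rs <- detect_events(simswap$gene, simswap$table, simswap$coverage, sf1)
  expect_equal(rs$delta_psi, -r1$delta_psi)
  expect_equal(rs$delta_ratio, -r1$delta_ratio)
  expect_equal(rs$psi_pvalue, r1$psi_pvalue)
  expect_equal(rs$ratio_pvalue, r1$ratio_pvalue)
})

test_that("detection power does not drop when depth grows", {
  set.seed(202)
  rate <- function(depth) {
    hits <- vapply(1:25, function(i) {
      sim <- cassette_sim(sample.int(1e6, 1L), depth = depth)
      sf <- user_size_factors(setNames(rep(1, 6L), sim$coverage$samples))
      res <- detect_events(sim$gene, sim$table, sim$coverage, sf)
      any(res$meta_exon_start == sim$truth$meta_exon_start)
    }, logical(1L))
    mean(hits)
  }
  expect_gte(rate(200), rate(20))
})

test_that("a novel best pair is reported alongside the best known pair", {
  g <- gene_model("G", "c", "+", list(
    list(id = "t1", exons = data.frame(start = c(0L, 200L, 400L),
                                       end = c(100L, 300L, 500L))),
    list(id = "t2", exons = data.frame(start = c(0L, 400L),
                                       end = c(100L, 500L)))))
  # novel exclusion junction (150 -> 400) has the extreme delta
  mk <- function(incl, excl, novel)
    jdf("c", c(100L, 100L, 150L), c(200L, 400L, 400L), c(incl, excl, novel))
  tab <- make_table(list(a1 = mk(50, 50, 0), a2 = mk(55, 45, 0),
                         b1 = mk(30, 70, 100), b2 = mk(28, 72, 110)),
                    annotation = g)
  expect_equal(sum(!tab$junctions$known), 1L)
  meta <- build_meta_exons(g)[2L, ]
  prs <- enumerate_pairs(tab, meta)
  sf <- rep(1, 4L)
  conds <- c("A", "A", "B", "B")
  scores <- lapply(seq_len(nrow(prs)), function(k)
    score_pair(tab, prs$incl[k], prs$excl[k], sf, conds, "A", "B"))
  bp <- best_pair(prs, scores, tab)
  expect_true(prs$uses_novel[bp$best])
  expect_false(is.na(bp$best_known))
  expect_false(prs$uses_novel[bp$best_known])
  # exhaustive check: the novel pair's delta beats every known-only delta
  deltas <- vapply(scores, function(s) abs(s$delta), numeric(1L))
  expect_equal(bp$best, which.max(deltas))
  expect_equal(deltas[bp$best_known],
               max(deltas[!prs$uses_novel]))
})
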