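## Seeded generator of gene models, junction counts and coverage tracks
## with known ground truth, in exactly the formats the readers consume.

#' Define a simulation scenario
#'
#' Describes a single-gene experiment with one cassette exon whose
#' inclusion level (true PSI) differs between two conditions. Junction
#' reads follow `incl ~ Binomial(N_s, PSI_c)`, `excl = N_s - incl` with
#' `N_s ~ Poisson(depth * libsize_s)`; constitutive junctions are
#' independent `Poisson(depth * libsize_s)`. Exonic coverage is
#' piecewise-constant at the isoform-weighted depth with optional per-base
#' Poisson noise.
#'
#' @param seed RNG seed (integer).
#' @param n_per_condition samples per condition (default 3).
#' @param depth mean reads per junction and mean per-base exonic coverage
#'   (default 200).
#' @param psi named vector of true cassette-exon PSI per condition
#'   (default `c(A = 0.8, B = 0.3)`); names define the condition labels.
#' @param libsizes per-sample relative library sizes (recycled per
#'   condition order); default all 1.
#' @param n_exons number of exons (>= 3, default 5).
#' @param exon_len,intron_len exon and intron lengths in bases (defaults
#'   200 and 300).
#' @param cassette index of the cassette exon (internal; default the middle
#'   exon).
#' @param noise coverage noise model: `"poisson"` (default) or `"none"`
#'   (exact expected coverage).
#' @param antisense if `TRUE`, the annotation additionally contains an
#'   antisense gene whose single exon overlaps the cassette exon.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L, n_per_condition = 3L, depth = 200,
                         psi = c(A = 0.8, B = 0.3), libsizes = NULL,
                         n_exons = 5L, exon_len = 200L, intron_len = 300L,
                         cassette = NULL, noise = c("poisson", "none"),
                         antisense = FALSE) {
  noise <- match.arg(noise)
  if (is.null(names(psi)) || length(psi) < 2L)
    stop("psi must be a named vector with one entry per condition")
  if (any(psi < 0 | psi > 1)) stop("true PSI values must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (n_exons < 3L) stop("need >= 3 exons for an internal cassette exon")
  if (is.null(cassette)) cassette <- (n_exons + 1L) %/% 2L
  if (cassette <= 1L || cassette >= n_exons)
    stop("cassette exon must be internal")
  n_samp <- n_per_condition * length(psi)
  if (is.null(libsizes)) libsizes <- rep(1, n_samp)
  if (length(libsizes) != n_samp)
    stop("libsizes must have one entry per sample (", n_samp, ")")
  structure(list(seed = as.integer(seed), n_per_condition = n_per_condition,
                 depth = depth, psi = psi, libsizes = libsizes,
                 n_exons = n_exons, exon_len = exon_len,
                 intron_len = intron_len, cassette = cassette,
                 noise = noise, antisense = antisense,
                 chrom = "chrS", origin = 1000L),
            class = "sim_scenario")
}

#' Gene model for a scenario
#'
#' Two annotated isoforms: one including all exons, one skipping the
#' cassette exon. Deterministic given the scenario (no randomness).
#'
#' @param scenario a [sim_scenario()].
#' @return list with `gene` (the query [gene_model]) and `annotation`
#'   (list of gene models; includes an antisense gene when requested).
#' @export
simulate_gene <- function(scenario) {
  s <- scenario
  starts <- s$origin + (seq_len(s$n_exons) - 1L) * (s$exon_len + s$intron_len)
  exons <- data.frame(start = starts, end = starts + s$exon_len)
  gene <- gene_model("SIMGENE", s$chrom, "+", list(
    list(id = "SIMGENE.incl", exons = exons),
    list(id = "SIMGENE.skip", exons = exons[-s$cassette, ])))
  annotation <- list(gene)
  if (isTRUE(s$antisense)) {
    cas <- exons[s$cassette, ]
    anti <- gene_model("SIMANTI", s$chrom, "-", list(
      list(id = "SIMANTI.t1",
           exons = data.frame(start = cas$start - 20L, end = cas$end + 20L))))
    annotation <- c(annotation, list(anti))
  }
  list(gene = gene, annotation = annotation)
}

sim_samples <- function(scenario) {
  conds <- rep(names(scenario$psi), each = scenario$n_per_condition)
  data.frame(sample = paste(conds,
                            rep(seq_len(scenario$n_per_condition),
                                times = length(scenario$psi)), sep = "_"),
             condition = conds, libsize = scenario$libsizes,
             stringsAsFactors = FALSE)
}

#' Simulate junction counts and coverage in memory
#'
#' Draws all counts under the scenario's model and returns ready-to-use
#' objects (no file I/O); [simulate_reads()] writes the same draws to disk.
#' Fully deterministic given the scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `gene`, `annotation`, `samples` (data.frame),
#'   `junctions` (named list of per-sample junction data.frames in
#'   [read_junction_file()] layout), `table` (merged `junction_table`),
#'   `coverage` (`coverage_set`), and `truth` (data.frame with the cassette
#'   meta-exon interval, per-condition true PSI and the true delta).
#' @export
simulate_counts <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  sim <- simulate_gene(s)
  gene <- sim$gene
  samples <- sim_samples(s)
  exons <- gene$transcripts[["SIMGENE.incl"]]$exons
  cas <- s$cassette
  ## annotated introns of the inclusion isoform; cassette-adjacent introns
  ## are the inclusion junctions, up->down is the exclusion junction
  intr <- data.frame(donor_end = exons$end[-nrow(exons)],
                     acceptor_start = exons$start[-1L])
  incl_idx <- c(cas - 1L, cas)             # introns flanking the cassette
  excl <- c(donor_end = exons$end[cas - 1L], acceptor_start = exons$start[cas + 1L])
  span_len <- gene$end - gene$start
  covmat <- matrix(0, span_len, nrow(samples),
                   dimnames = list(NULL, samples$sample))
  juncs <- vector("list", nrow(samples))
  for (k in seq_len(nrow(samples))) {
    lib <- samples$libsize[k]
    p_true <- s$psi[[samples$condition[k]]]
    n_cas <- rpois(1L, s$depth * lib)
    n_incl <- rbinom(1L, n_cas, p_true)
    n_excl <- n_cas - n_incl
    cnt <- rpois(nrow(intr), s$depth * lib)
    cnt[incl_idx] <- n_incl
    jd <- rbind(
      data.frame(chrom = s$chrom, donor_end = intr$donor_end,
                 acceptor_start = intr$acceptor_start, strand = "*",
                 count = cnt, stringsAsFactors = FALSE),
      data.frame(chrom = s$chrom, donor_end = excl[["donor_end"]],
                 acceptor_start = excl[["acceptor_start"]], strand = "*",
                 count = n_excl, stringsAsFactors = FALSE))
    juncs[[k]] <- jd[jd$count > 0, , drop = FALSE]
    mu <- numeric(span_len)
    for (i in seq_len(nrow(exons))) {
      rows <- (exons$start[i] - gene$start + 1L):(exons$end[i] - gene$start)
      mu[rows] <- s$depth * lib * if (i == cas) p_true else 1
    }
    covmat[, k] <- if (s$noise == "poisson") rpois(span_len, mu) else mu
  }
  names(juncs) <- samples$sample
  table <- merge_junction_tables(juncs, sim$annotation)
  coverage <- structure(list(chrom = s$chrom, start = gene$start,
                             end = gene$end, mat = covmat,
                             samples = samples$sample,
                             conditions = samples$condition),
                        class = "coverage_set")
  truth <- data.frame(chrom = s$chrom, meta_exon_start = exons$start[cas],
                      meta_exon_end = exons$end[cas],
                      t(setNames(as.numeric(s$psi),
                                 paste0("true_psi_", names(s$psi)))),
                      true_delta = abs(s$psi[[1L]] - s$psi[[2L]]))
  list(gene = gene, annotation = sim$annotation, samples = samples,
       junctions = juncs, table = table, coverage = coverage, truth = truth)
}

#' Write a simulated data set to disk
#'
#' Produces exactly the formats the readers consume: per-sample junction
#' files (minimal TSV or STAR SJ.out.tab dialect), per-sample coverage
#' tracks (bedgraph by default, bigwig optional), the annotation GTF, a
#' project TSV and a ground-truth TSV.
#'
#' @param scenario a [sim_scenario()].
#' @param dir output directory (created if needed).
#' @param dialect junction file dialect to write.
#' @param coverage_format `"bedgraph"` (default) or `"bigwig"`.
#' @return list with `project` (project TSV path), `gtf`, `truth`, `dir`
#'   and the in-memory simulation under `sim`.
#' @export
simulate_reads <- function(scenario, dir,
                           dialect = c("minimal_tsv", "star_sj"),
                           coverage_format = c("bedgraph", "bigwig")) {
  dialect <- match.arg(dialect)
  coverage_format <- match.arg(coverage_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(scenario)
  gene <- sim$gene
  samples <- sim$samples
  jpaths <- cpaths <- character(nrow(samples))
  for (k in seq_len(nrow(samples))) {
    id <- samples$sample[k]
    jd <- sim$junctions[[id]]
    if (dialect == "minimal_tsv") {
      jpaths[k] <- paste0(id, ".junctions.tsv")
      write.table(jd[, c("chrom", "donor_end", "acceptor_start", "count")],
                  file.path(dir, jpaths[k]), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else {
      jpaths[k] <- paste0(id, ".SJ.out.tab")
      star <- data.frame(jd$chrom, jd$donor_end + 1L, jd$acceptor_start,
                         1L, 1L, 1L, jd$count, 0L, 30L)
      write.table(star, file.path(dir, jpaths[k]), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    v <- sim$coverage$mat[, k]
    rl <- rle(v)
    ends <- gene$start + cumsum(rl$lengths)
    starts <- ends - rl$lengths
    keep <- rl$values != 0
    gr <- GenomicRanges::GRanges(
      scenario$chrom, IRanges::IRanges(starts[keep] + 1L, ends[keep]),
      score = rl$values[keep])
    if (coverage_format == "bedgraph") {
      cpaths[k] <- paste0(id, ".bedgraph")
      rtracklayer::export(gr, file.path(dir, cpaths[k]), format = "bedGraph")
    } else {
      cpaths[k] <- paste0(id, ".bw")
      GenomeInfoDb::seqlengths(gr) <-
        setNames(gene$end + 10000L, scenario$chrom)
      rtracklayer::export(gr, file.path(dir, cpaths[k]), format = "BigWig")
    }
  }
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(sim$annotation, gtf)
  project <- data.frame(sample = samples$sample,
                        condition = samples$condition,
                        bigwig = cpaths, junctions = jpaths,
                        stringsAsFactors = FALSE)
  ppath <- file.path(dir, "project.tsv")
  write.table(project, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  tpath <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(project = ppath, gtf = gtf, truth = tpath, dir = dir, sim = sim)
}
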