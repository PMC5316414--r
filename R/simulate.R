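# Synthetic TEF-seq/NET-seq data with ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# phased nucleosomes, Pol2 tracks with a 5' peak and a pre-PAS peak, TEF
# tracks equal to Pol2 times a gene-specific enrichment times a
# nucleosome-phased oscillation, a "degraded mature RNA" background spread
# uniformly over each gene's transcript span (shared, up to a global scalar,
# by tagged and no-tag samples, and dominated at a Pol3-like control gene),
# and NB count sampling with overdispersion.

#' Simulation configuration with desk-scale defaults
#'
#' @param n_genes number of Pol2-transcribed genes (default 200).
#' @param gene_length length-2 range of gene lengths in nt (default
#'   600-3000).
#' @param chrom_lengths named integer vector of chromosome lengths (default
#'   two 400-kb chromosomes).
#' @param frac_divergent fraction of genes arranged as divergent promoter
#'   pairs (default 0.2).
#' @param rate_meanlog,rate_sdlog log-normal per-gene transcription-rate
#'   parameters (defaults 0 and 0.8).
#' @param enrichment_values,enrichment_probs point masses of the per-gene
#'   log2 TEF enrichment distribution (defaults 0 / +1.5 / -1.5 with
#'   probabilities 0.9 / 0.05 / 0.05).
#' @param osc_amplitude fractional amplitude of the nucleosome-phased TEF
#'   oscillation (default 0.2).
#' @param osc_period oscillation period in nt (default 165, the nucleosome
#'   repeat length).
#' @param osc_phase phase at the dyad in radians (default `pi`: TEF minimum
#'   at the dyad center, maximum ~82 nt away).
#' @param peak5_height,peak5_width 5' Pol2 peak: excess height over body and
#'   exponential decay length in nt (defaults 2 and 80).
#' @param peak3_height,peak3_width pre-PAS Pol2 peak (defaults 1 and 50).
#' @param contamination fraction of tagged-library reads that are mature-RNA
#'   background (default 0.25); this is also the true tagged/no-tag
#'   background ratio at equal depths.
#' @param control_bg_weight fraction of total background mass placed on the
#'   Pol3-like control gene (default 0.05).
#' @param nuc_first transcription-direction offset of the first dyad from the
#'   TSS (default 100 nt).
#' @param dispersion NB dispersion alpha, variance `mu + alpha mu^2`
#'   (default 0.05; 0 gives Poisson counts).
#' @param reads_per_sample expected library size (default 1e6).
#' @param n_replicates replicates per IP factor (default 2).
#' @param read_length nominal aligned read length for emitted read records
#'   (default 50).
#' @param seed integer RNG seed (default 1).
#' @return a list of class `tefseq_sim_config`.
#' @export
simulationConfig <- function(n_genes = 200L, gene_length = c(600L, 3000L),
                             chrom_lengths = c(chrI = 400000L,
                                               chrII = 400000L),
                             frac_divergent = 0.2,
                             rate_meanlog = 0, rate_sdlog = 0.8,
                             enrichment_values = c(0, 1.5, -1.5),
                             enrichment_probs = c(0.9, 0.05, 0.05),
                             osc_amplitude = 0.2, osc_period = 165,
                             osc_phase = pi,
                             peak5_height = 2, peak5_width = 80,
                             peak3_height = 1, peak3_width = 50,
                             contamination = 0.25, control_bg_weight = 0.05,
                             nuc_first = 100L,
                             dispersion = 0.05, reads_per_sample = 1e6,
                             n_replicates = 2L, read_length = 50L,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(frac_divergent >= 0, frac_divergent <= 1,
            contamination >= 0, contamination <= 1,
            osc_period > 0, dispersion >= 0,
            abs(sum(enrichment_probs) - 1) < 1e-8)
  class(cfg) <- "tefseq_sim_config"
  cfg
}

#' Simulate a genome layout: annotations, nucleosome map, divergent truth
#'
#' Places non-overlapping genes on both strands of the configured
#' chromosomes. The requested fraction of genes is arranged as divergent
#' pairs (a minus-strand and a plus-strand gene transcribed away from each
#' other, TSS separation drawn from (0, 1200]); remaining genes are spaced
#' far enough apart (> 1300 nt between units) that no chance divergent pairs
#' arise. Nucleosome dyads are phased every `osc_period` nt from each TSS
#' (first dyad at `nuc_first`). One extra high-background Pol3-like control
#' gene (biotype `"other"`) is added for background calibration.
#'
#' @param config a [simulationConfig()].
#' @return list with `genes` (annotation table; `rate` and `enrichment`
#'   columns carry the truth), `nucmap`, `true_pairs` (data.frame gene1,
#'   gene2, separation), `control_gene` (id).
#' @export
makeGenomeAndAnnotations <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  n_pairs <- floor(config$frac_divergent * n / 2)
  n_single <- n - 2L * n_pairs
  lens <- as.integer(round(stats::runif(n + 1L, config$gene_length[1],
                                        config$gene_length[2])))
  unit_type <- sample(c(rep("pair", n_pairs), rep("single", n_single),
                        "control"))
  gap <- function() as.integer(1400L + round(stats::runif(1, 0, 400)))

  chroms <- names(config$chrom_lengths)
  cursor <- stats::setNames(rep(1000L, length(chroms)), chroms)
  ci <- 1L
  gi <- 1L
  rows <- list(); true_pairs <- list(); control_gene <- NA_character_
  for (ut in unit_type) {
    need <- if (ut == "pair") lens[gi] + lens[gi + 1L] + 1300L else lens[gi]
    # advance to a chromosome with room; reject if none fits
    tries <- 0L
    while (cursor[ci] + need + 2000L > config$chrom_lengths[ci]) {
      ci <- ci %% length(chroms) + 1L
      tries <- tries + 1L
      if (tries > length(chroms))
        stop("infeasible packing: genes do not fit on the configured ",
             "chromosomes; reduce n_genes or gene lengths")
    }
    ch <- chroms[ci]
    if (ut == "pair") {
      lenA <- lens[gi]; lenB <- lens[gi + 1L]
      sep <- as.integer(round(stats::runif(1, 100, 1200)))
      startA <- cursor[ci]
      tssA <- startA + lenA - 1L          # minus-strand gene, TSS at right
      tssB <- tssA + sep                  # plus-strand gene, TSS at left
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%04d", gi), chrom = ch, strand = "-",
        start = startA, end = startA + lenA, biotype = "mRNA")
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("g%04d", gi + 1L), chrom = ch, strand = "+",
        start = tssB, end = tssB + lenB, biotype = "mRNA")
      true_pairs[[length(true_pairs) + 1L]] <- data.frame(
        gene1 = sprintf("g%04d", gi), gene2 = sprintf("g%04d", gi + 1L),
        separation = sep)
      cursor[ci] <- tssB + lenB + gap()
      gi <- gi + 2L
    } else {
      len <- lens[gi]
      strand <- sample(c("+", "-"), 1)
      id <- if (ut == "control") "ctrlPol3" else sprintf("g%04d", gi)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = id, chrom = ch, strand = strand,
        start = cursor[ci], end = cursor[ci] + len,
        biotype = if (ut == "control") "other" else "mRNA")
      if (ut == "control") control_gene <- id else gi <- gi + 1L
      cursor[ci] <- cursor[ci] + len + gap()
    }
    ci <- ci %% length(chroms) + 1L
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  validateAnnotations(genes)

  is_ctrl <- genes$gene_id == control_gene
  genes$rate <- stats::rlnorm(nrow(genes), config$rate_meanlog,
                              config$rate_sdlog)
  genes$enrichment <- sample(config$enrichment_values, nrow(genes),
                             replace = TRUE, prob = config$enrichment_probs)
  genes$enrichment[is_ctrl] <- 0
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL

  # phased dyads from each TSS (transcription direction), within the gene
  nucmap <- lapply(stats::setNames(chroms, chroms), function(ch) integer())
  tss <- geneTss(genes); len <- geneLength(genes)
  for (i in seq_len(nrow(genes))) {
    if (genes$gene_id[i] == control_gene) next
    if (config$nuc_first > len[i] - 50L) next
    u <- seq.int(config$nuc_first, len[i] - 50L, by = round(config$osc_period))
    if (!length(u)) next
    d <- if (genes$strand[i] == "+") tss[i] + u else tss[i] - u
    nucmap[[genes$chrom[i]]] <- c(nucmap[[genes$chrom[i]]], as.integer(d))
  }
  nucmap <- lapply(nucmap, function(p) sort(unique(p)))

  tp <- if (length(true_pairs)) do.call(rbind, true_pairs)
        else data.frame(gene1 = character(), gene2 = character(),
                        separation = integer())
  tp <- tp[order(tp$gene1), , drop = FALSE]
  rownames(tp) <- NULL
  list(genes = genes, nucmap = nucmap, true_pairs = tp,
       control_gene = control_gene)
}

#' Ground-truth expected-signal tracks
#'
#' Builds per-nucleotide expectation tracks (state `"expected"`) for Pol2,
#' TEF and the mature-RNA background. Pol2 expectation is
#' `rate * shape(u)` with `shape(u) = 1 + peak5 * exp(-u/width5) +
#' peak3 * exp(-(L-1-u)/width3)` in transcription-direction coordinate `u`;
#' TEF is `Pol2 * 2^enrichment * max(0, 1 + A cos(2*pi*(x - d1)/period +
#' phase))` with `d1` the gene's first dyad; background is uniform over each
#' gene span with mass proportional to `rate * length` (the control gene
#' carries `control_bg_weight` of the total background mass and no Pol2/TEF
#' signal). Deterministic given the genome layout.
#'
#' @param genome result of [makeGenomeAndAnnotations()].
#' @param config the [simulationConfig()].
#' @return list of [StrandedTrack-class]: `pol2`, `tef`, `background`.
#' @export
simulateTracks <- function(genome, config) {
  genes <- genome$genes
  sl <- config$chrom_lengths
  mk <- function() lapply(stats::setNames(names(sl), names(sl)),
                          function(ch) numeric(sl[[ch]]))
  pol2 <- list(`+` = mk(), `-` = mk())
  tef <- list(`+` = mk(), `-` = mk())
  bg <- list(`+` = mk(), `-` = mk())
  tss <- geneTss(genes); len <- geneLength(genes)

  bg_mass <- genes$rate * len
  is_ctrl <- genes$gene_id == genome$control_gene
  w <- config$control_bg_weight
  if (any(is_ctrl) && w > 0)
    bg_mass[is_ctrl] <- w / (1 - w) * sum(bg_mass[!is_ctrl])

  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; s <- genes$strand[i]
    u <- 0:(len[i] - 1L)
    idx <- (genes$start[i] + 1L):genes$end[i]     # vector indices
    if (s == "-") u <- rev(u)                      # u in transcription dir
    if (!is_ctrl[i]) {
      shape <- 1 + config$peak5_height * exp(-u / config$peak5_width) +
        config$peak3_height * exp(-(len[i] - 1L - u) / config$peak3_width)
      p <- genes$rate[i] * shape
      dy <- nucleosomeInstances(genes[i, , drop = FALSE], genome$nucmap)
      x <- genes$start[i]:(genes$end[i] - 1L)      # genomic positions
      osc <- if (nrow(dy) > 0) {
        d1 <- dy$dyad[which.min(dy$u)]
        pmax(0, 1 + config$osc_amplitude *
               cos(2 * pi * (x - d1) / config$osc_period + config$osc_phase))
      } else rep(1, len[i])
      pol2[[s]][[ch]][idx] <- pol2[[s]][[ch]][idx] + p
      tef[[s]][[ch]][idx] <- tef[[s]][[ch]][idx] +
        p * 2^genes$enrichment[i] * osc
    }
    bg[[s]][[ch]][idx] <- bg[[s]][[ch]][idx] + bg_mass[i] / len[i]
  }
  list(pol2 = strandedTrack(pol2[["+"]], pol2[["-"]], sl, "pol2_truth",
                            "expected"),
       tef = strandedTrack(tef[["+"]], tef[["-"]], sl, "tef_truth",
                           "expected"),
       background = strandedTrack(bg[["+"]], bg[["-"]], sl, "bg_truth",
                                  "expected"))
}

.sampleCounts <- function(meanTrack, config) {
  sl <- seqlengths(meanTrack)
  draw <- function(mu) {
    if (config$dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  plus <- lapply(stats::setNames(names(sl), names(sl)),
                 function(ch) as.numeric(draw(trackSignal(meanTrack, ch, "+"))))
  minus <- lapply(stats::setNames(names(sl), names(sl)),
                  function(ch) as.numeric(draw(trackSignal(meanTrack, ch, "-"))))
  strandedTrack(plus, minus, sl, meanTrack@sample, "raw_counts")
}

.scaleTrack <- function(track, factor, sample = track@sample,
                        state = track@state) {
  strandedTrack(lapply(track@plus, `*`, factor),
                lapply(track@minus, `*`, factor),
                seqlengths(track), sample, state)
}

.addTracks <- function(a, b, sample = a@sample, state = a@state) {
  strandedTrack(Map(`+`, a@plus, b@plus), Map(`+`, a@minus, b@minus),
                seqlengths(a), sample, state)
}

#' Sample count tracks (and truth) for all IP samples
#'
#' For each sample the per-position mean is `(1 - c) * N * signal/mass(signal)
#' + c * N * bg/mass(bg)` for tagged IPs (TEF and Pol2, `c` =
#' `contamination`, `N` = `reads_per_sample`) and `N * bg/mass(bg)` for the
#' no-tag control, so at equal depths the true tagged/no-tag background ratio
#' equals `contamination`. Counts are NB with the configured dispersion;
#' replicates use consecutive sub-seeds of `config$seed`.
#'
#' @param tracks expectation tracks from [simulateTracks()].
#' @param config the [simulationConfig()].
#' @return list with `samples` (named list of raw-count
#'   [StrandedTrack-class]: `tef_rep1..n`, `pol2_rep1..n`, `notag`),
#'   `true_ratio` (tagged/no-tag background ratio) and `mean_tracks` (the
#'   per-sample expectation tracks).
#' @export
sampleReads <- function(tracks, config) {
  N <- config$reads_per_sample
  cc <- config$contamination
  bg_unit <- .scaleTrack(tracks$background,
                         1 / trackTotal(tracks$background))
  mk_mean <- function(sig, frac_sig, name) {
    m <- .scaleTrack(bg_unit, (1 - frac_sig) * N, name, "expected")
    if (frac_sig > 0)
      m <- .addTracks(.scaleTrack(sig, frac_sig * N / trackTotal(sig)), m,
                      sample = name, state = "expected")
    m
  }
  means <- list()
  for (r in seq_len(config$n_replicates)) {
    means[[paste0("tef_rep", r)]] <- mk_mean(tracks$tef, 1 - cc,
                                             paste0("tef_rep", r))
    means[[paste0("pol2_rep", r)]] <- mk_mean(tracks$pol2, 1 - cc,
                                              paste0("pol2_rep", r))
  }
  means[["notag"]] <- mk_mean(tracks$pol2, 0, "notag")
  samples <- list()
  for (k in seq_along(means)) {
    set.seed((config$seed * 1000 + k) %% 2147483647)
    samples[[names(means)[k]]] <- .sampleCounts(means[[k]], config)
  }
  list(samples = samples, true_ratio = cc, mean_tracks = means)
}

#' Expand a count track into 3'-end read records
#'
#' Emits one read per counted unit whose 3'-narrowing reproduces the track
#' exactly: a plus-strand count at position `p` becomes a read spanning
#' `[p - read_length + 1, p + 1)` (clipped at the chromosome start), a
#' minus-strand count a read spanning `[p, p + read_length)` (clipped at the
#' end).
#'
#' @param track a raw-count [StrandedTrack-class].
#' @param read_length nominal read length (default 50).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
readsFromCounts <- function(track, read_length = 50L) {
  sl <- seqlengths(track)
  res <- list()
  for (ch in names(sl)) {
    for (s in c("+", "-")) {
      v <- trackSignal(track, ch, s)
      nz <- which(v > 0)
      if (!length(nz)) next
      p <- rep(nz - 1L, times = v[nz])          # 0-based 3' positions
      if (s == "+") {
        start <- pmax(0L, p - read_length + 1L); end <- p + 1L
      } else {
        start <- p; end <- pmin(sl[[ch]], p + read_length)
      }
      res[[length(res) + 1L]] <- data.frame(chrom = ch, start = start,
                                            end = end, strand = s)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
  rownames(out) <- NULL
  out
}

#' Write read records as a minimal SAM file
#'
#' @param reads read table (`chrom`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @param seqlengths named chromosome lengths for the header.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "+", 0L, 16L)
    writeLines(sprintf("r%07d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(reads)), flag, reads$chrom,
                       reads$start + 1L, reads$end - reads$start), con)
  }
  invisible(path)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome layout, expectation tracks and sampled count
#' tracks, plus the truth tables needed to score every downstream stage.
#' Byte-identical for identical config (including seed).
#'
#' @param config a [simulationConfig()].
#' @return list with `genes`, `nucmap`, `true_pairs`, `control_gene`,
#'   `truth_tracks`, `samples`, `true_ratio`, `mean_tracks`, `config`.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  genome <- makeGenomeAndAnnotations(config)
  tracks <- simulateTracks(genome, config)
  sampled <- sampleReads(tracks, config)
  c(genome, list(truth_tracks = tracks, samples = sampled$samples,
                 true_ratio = sampled$true_ratio,
                 mean_tracks = sampled$mean_tracks, config = config))
}
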