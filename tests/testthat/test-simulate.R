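# Small configs keep the suite fast; the acceptance tests exercise the
# full default scale.
smallConfig <- function(...) {
  defaults <- list(n_genes = 30L,
                   chrom_lengths = c(chrI = 120000L, chrII = 120000L),
                   reads_per_sample = 2e5)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

test_that("generator is deterministic and honours the divergent fraction", {
  cfg <- smallConfig(seed = 5L)
  a <- makeGenomeAndAnnotations(cfg)
  b <- makeGenomeAndAnnotations(cfg)
  expect_identical(a, b)
  # truth pairs are exactly what findDivergentPairs recovers
  mrna <- a$genes[a$genes$biotype == "mRNA", ]
  found <- pairTable(findDivergentPairs(mrna))
  expect_equal(found$gene1, a$true_pairs$gene1)
  expect_equal(found$gene2, a$true_pairs$gene2)
  expect_equal(found$separation, a$true_pairs$separation)
  expect_equal(nrow(found), floor(0.2 * 30 / 2))
  # no divergent pairs requested -> none found
  cfg0 <- smallConfig(seed = 6L, frac_divergent = 0)
  g0 <- makeGenomeAndAnnotations(cfg0)
  expect_equal(nrow(pairTable(findDivergentPairs(
    g0$genes[g0$genes$biotype == "mRNA", ]))), 0L)
  # two genes arranged divergent at a known separation
  cfg2 <- simulationConfig(n_genes = 2L, frac_divergent = 1,
                           chrom_lengths = c(chrI = 50000L), seed = 3L)
  g2 <- makeGenomeAndAnnotations(cfg2)
  expect_equal(nrow(pairTable(findDivergentPairs(
    g2$genes[g2$genes$biotype == "mRNA", ]))), 1L)
  # infeasible packing is rejected
  expect_error(makeGenomeAndAnnotations(
    simulationConfig(n_genes = 100L, chrom_lengths = c(chrI = 10000L))),
    "infeasible")
})

test_that("expected tracks obey the generative identities", {
  # no oscillation, flat shape: TEF/Pol2 = 2^enrichment everywhere
  cfg <- smallConfig(seed = 11L, osc_amplitude = 0, peak5_height = 0,
                     peak3_height = 0)
  genome <- makeGenomeAndAnnotations(cfg)
  tracks <- simulateTracks(genome, cfg)
  g <- genome$genes[genome$genes$biotype == "mRNA", ][1, ]
  e <- g$enrichment
  idx <- (g$start + 1L):g$end
  p <- trackSignal(tracks$pol2, g$chrom, g$strand)[idx]
  t <- trackSignal(tracks$tef, g$chrom, g$strand)[idx]
  expect_equal(t, 2^e * p, tolerance = 1e-12)
  expect_equal(p, rep(g$rate, length(idx)), tolerance = 1e-12)
  # enrichment 0 and amplitude 0: TEF identical to Pol2
  cfg0 <- smallConfig(seed = 12L, osc_amplitude = 0,
                      enrichment_values = 0, enrichment_probs = 1)
  genome0 <- makeGenomeAndAnnotations(cfg0)
  tracks0 <- simulateTracks(genome0, cfg0)
  expect_equal(trackSignal(tracks0$tef, "chrI", "+"),
               trackSignal(tracks0$pol2, "chrI", "+"), tolerance = 1e-12)
  # control gene carries background but no Pol2/TEF signal
  ctrl <- genome$genes[genome$genes$gene_id == genome$control_gene, ]
  cidx <- (ctrl$start + 1L):ctrl$end
  expect_true(all(trackSignal(tracks$pol2, ctrl$chrom, ctrl$strand)[cidx]
                  == 0))
  expect_true(all(trackSignal(tracks$background, ctrl$chrom,
                              ctrl$strand)[cidx] > 0))
})

test_that("the oscillation averages out over one period (quadrature)", {
  cfg <- smallConfig(seed = 13L, peak5_height = 0, peak3_height = 0,
                     gene_length = c(2000L, 3000L))
  genome <- makeGenomeAndAnnotations(cfg)
  tracks <- simulateTracks(genome, cfg)
  g <- genome$genes[genome$genes$biotype == "mRNA", ][2, ]
  inst <- nucleosomeInstances(g, genome$nucmap)
  d1 <- inst$dyad[which.min(inst$u)]
  # one full period starting at the first dyad, inside the gene
  pos <- if (g$strand == "+") d1:(d1 + 164L) else d1:(d1 - 164L)
  t <- trackSignal(tracks$tef, g$chrom, g$strand)[pos + 1L]
  p <- trackSignal(tracks$pol2, g$chrom, g$strand)[pos + 1L]
  expect_equal(mean(t / p), 2^g$enrichment, tolerance = 1e-6)
  # phase: minimum of TEF/Pol2 at the dyad (phase pi), maximum ~82 nt away
  r <- t / p
  expect_equal(which.min(abs(r - min(r))), 1L)
  expect_equal(abs(which.max(r) - 1L - 82.5) < 3, TRUE)
})

test_that("sampled counts conserve mass into read records and hit targets", {
  cfg <- smallConfig(seed = 21L, dispersion = 0)
  ds <- simulateDataset(cfg)
  tr <- ds$samples$tef_rep1
  # Poisson totals land within 3 SE of the configured library size
  expect_lt(abs(trackTotal(tr) - cfg$reads_per_sample),
            3 * sqrt(cfg$reads_per_sample))
  reads <- readsFromCounts(tr)
  expect_equal(nrow(reads), trackTotal(tr))
  # narrowing the emitted reads reproduces the counts exactly
  back <- narrowTo3Prime(reads, seqlengths(tr))
  for (s in c("+", "-"))
    expect_identical(trackSignal(back, "chrI", s),
                     trackSignal(tr, "chrI", s))
  # determinism of the full dataset
  ds2 <- simulateDataset(cfg)
  expect_identical(trackSignal(ds2$samples$pol2_rep2, "chrII", "-"),
                   trackSignal(ds$samples$pol2_rep2, "chrII", "-"))
})

test_that("no-tag contamination of zero makes the control ratio vanish", {
  cfg <- smallConfig(seed = 31L, contamination = 0)
  ds <- simulateDataset(cfg)
  ctrl <- ds$genes[ds$genes$gene_id == ds$control_gene, ]
  m <- fitScr1Ratio(ds$samples$tef_rep1, ds$samples$notag,
                    region = list(chrom = ctrl$chrom, start = ctrl$start,
                                  end = ctrl$end, strand = ctrl$strand))
  expect_lt(backgroundRatio(m), 0.01)
})

test_that("pipeline smoke run writes a reproducible manifest", {
  cfg <- smallConfig(seed = 41L, reads_per_sample = 1e5)
  out1 <- file.path(tempdir(), "run1"); out2 <- file.path(tempdir(), "run2")
  m1 <- runPipeline(cfg, out1, permutation_samples = 200L)
  expected <- c("annotations.bed", "background_model.json", "counts.tsv",
                "differential.tsv", "divergent_pairs.tsv",
                "profile_pol2_tss.tsv", "profile_ratio_tss.tsv",
                "profile_nucleosome.tsv", "heatmap_pol2.tsv",
                "pair_enrichment.json")
  expect_true(all(expected %in% names(m1$outputs)))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  # identical config -> identical checksums
  m2 <- runPipeline(cfg, out2, permutation_samples = 200L)
  expect_identical(m1$outputs, m2$outputs)
  # toggling differential off removes only differential outputs
  out3 <- file.path(tempdir(), "run3")
  m3 <- runPipeline(cfg, out3, stages = c("background", "profiles", "pairs"),
                    permutation_samples = 200L)
  expect_false("differential.tsv" %in% names(m3$outputs))
  expect_identical(m3$outputs[["profile_pol2_tss.tsv"]],
                   m1$outputs[["profile_pol2_tss.tsv"]])
})
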