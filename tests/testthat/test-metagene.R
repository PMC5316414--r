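# One long chromosome with a handful of well-separated genes.
metageneFixture <- function(n_genes = 20L, gene_len = 2000L, spacing = 3000L,
                            chrom_len = NULL, strands = NULL) {
  if (is.null(chrom_len)) chrom_len <- n_genes * spacing + 4000L
  start <- 2000L + (seq_len(n_genes) - 1L) * spacing
  if (is.null(strands)) strands <- rep(c("+", "-"), length.out = n_genes)
  data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)), chrom = "chrI",
             strand = strands, start = start, end = start + gene_len,
             biotype = "mRNA", chrom_len = chrom_len)
}

constantTrack <- function(genes, value = 1, state = "expected") {
  len <- genes$chrom_len[1]
  makeTrackFromVectors(rep(value, len), rep(value, len), state = state)
}

test_that("trimmed mean uses floor counts and worked examples hold", {
  expect_equal(trimmedMean(1:20, 0.05), mean(2:19))  # 10.5
  expect_equal(trimmedMean(1:20, 0.05), 10.5)
  expect_equal(trimmedMean(rep(3, 50), 0.10), 3)     # constants unaffected
  expect_equal(trimmedMean(c(NA, 1, 2, 3), 0), 2)
  expect_true(is.na(trimmedMean(numeric(0), 0.05)))
  # floor rule: n = 19, trim 0.05 -> k = 0, nothing trimmed
  expect_equal(trimmedMean(1:19, 0.05), mean(1:19))
  expect_equal(trimValues(1:20, 0.05), 2:19)
})

test_that("standard profile of a constant track is constant (bin * value)", {
  genes <- metageneFixture()
  tr <- constantTrack(genes, 2)
  prof <- standardProfile(tr, genes, "TSS")
  v <- profileValues(prof)
  expect_true(all(abs(v - 20) < 1e-9))   # 10-nt bins of constant 2
  # trimmed mean equals untrimmed mean when all genes are identical
  prof0 <- standardProfile(tr, genes, "TSS", trim = 0)
  expect_equal(profileValues(prof0), v)
})

test_that("standard profile matches a sort-and-slice brute-force oracle", {
  set.seed(61)
  genes <- metageneFixture()
  len <- genes$chrom_len[1]
  tr <- makeTrackFromVectors(as.numeric(rpois(len, 2)),
                             as.numeric(rpois(len, 2)))
  for (anchor in c("TSS", "PAS")) {
    prof <- standardProfile(tr, genes, anchor)
    offs <- profileOffsets(prof)
    gl <- genes$end - genes$start
    oracle <- vapply(seq_along(offs), function(j) {
      vals <- numeric(0)
      for (i in seq_len(nrow(genes))) {
        L <- gl[i]
        if (anchor == "PAS" && L <= 500L) next
        off <- offs[j]
        # per-gene exclusion zones
        if (anchor == "TSS" && off + 10L - 1L >= L - 200L) next
        if (anchor == "PAS" && off < 501L - L) next
        s <- genes$strand[i]
        a <- if (anchor == "TSS") {
          if (s == "+") genes$start[i] else genes$end[i] - 1L
        } else {
          if (s == "+") genes$end[i] - 1L else genes$start[i]
        }
        pos <- if (s == "+") (a + off):(a + off + 9L)
               else (a - off):(a - off - 9L)
        v <- trackSignal(tr, "chrI", s)
        vals <- c(vals, sum(v[pos + 1L]))
      }
      n <- length(vals)
      k <- floor(0.05 * n)
      if (n == 0) return(NA_real_)
      mean(sort(vals)[(k + 1):(n - k)])
    }, numeric(1))
    expect_equal(unname(profileValues(prof)), oracle, tolerance = 1e-12)
  }
})

test_that("PAS profiles exclude short genes and TSS-proximal bins", {
  genes <- metageneFixture(n_genes = 4L, gene_len = 450L, spacing = 3000L)
  genes$end[3:4] <- genes$start[3:4] + 2000L   # two long genes
  tr <- constantTrack(genes, 1)
  prof <- standardProfile(tr, genes, "PAS")
  # only the two long genes can contribute anywhere
  expect_true(all(prof@n <= 2L))
  # bins at the far upstream edge lie within TSS+500 of a 2000-nt gene? no:
  # offset -400 maps to gene coord 1599 >= 500, so both genes contribute
  expect_equal(unname(prof@n[1]), 2L)
})

test_that("ratio profile: constant ratio, undefined-ratio handling, scaling", {
  genes <- metageneFixture()
  pol2 <- constantTrack(genes, 1)
  tef <- constantTrack(genes, 2)
  prof <- ratioProfile(tef, pol2, genes, "TSS",
                       scaling = c(X = 1), factor = "X")
  expect_true(all(abs(profileValues(prof) - 2) < 1e-9))
  # factor scaling multiplies the ratio
  prof22 <- ratioProfile(tef, pol2, genes, "TSS",
                         scaling = c(Paf1 = 2.2), factor = "Paf1")
  expect_true(all(abs(profileValues(prof22) - 4.4) < 1e-9))
  expect_error(ratioProfile(tef, pol2, genes, scaling = c(A = 1),
                            factor = "Paf1"), "no scaling factor")
  # zero Pol2 for one gene drops its ratios and reduces the bin count
  len <- genes$chrom_len[1]
  pv <- rep(1, len); mv <- rep(1, len)
  g1 <- genes[1, ]  # plus strand
  pv[(g1$start - 200L):(g1$end + 200L)] <- 0
  pol2z <- makeTrackFromVectors(pv, mv, state = "expected")
  profz <- ratioProfile(tef, pol2z, genes, "TSS",
                        scaling = c(X = 1), factor = "X")
  expect_true(all(profz@n < prof@n))
  expect_true(all(abs(profileValues(profz) - 2) < 1e-9))
})

test_that("profiles are invariant under genome mirror (strand symmetry)", {
  set.seed(77)
  genes <- metageneFixture()
  len <- genes$chrom_len[1]
  plus <- as.numeric(rpois(len, 2)); minus <- as.numeric(rpois(len, 2))
  tr <- makeTrackFromVectors(plus, minus)
  # mirror: reverse coordinates, swap strands
  mirror_genes <- genes
  mirror_genes$start <- len - genes$end
  mirror_genes$end <- len - genes$start
  mirror_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  tr_m <- makeTrackFromVectors(rev(minus), rev(plus))
  p1 <- standardProfile(tr, genes, "TSS")
  p2 <- standardProfile(tr_m, mirror_genes, "TSS")
  expect_equal(profileValues(p1), profileValues(p2), tolerance = 1e-12)
  expect_equal(p1@n, p2@n)
})

test_that("nucleosome instances and window extraction are exact", {
  gene <- makeGene("g1", strand = "+", start = 1000L, end = 3000L)
  gene$chrom_len <- 5000L
  dyads <- c(1100L, 1265L, 1430L, 1595L, 1030L)  # last is before TSS+50
  nucmap <- list(chrI = sort(dyads))
  inst <- nucleosomeInstances(gene, nucmap)
  # dyad at u=30 is inside the gene so it takes ordinal 1 but fails u > 50
  expect_equal(inst$ordinal, 2:5)
  expect_equal(inst$u, c(100L, 265L, 430L, 595L))
  # minus-strand gene mirrored
  geneM <- makeGene("g2", strand = "-", start = 1000L, end = 3000L)
  dyadsM <- c(2999L - 100L, 2999L - 265L)
  instM <- nucleosomeInstances(geneM, list(chrI = sort(dyadsM)))
  expect_equal(sort(instM$u), c(100L, 265L))
  # hand-extracted window check: impulse 10 nt downstream of a dyad
  len <- 5000L
  pv <- numeric(len); pv[(1100L + 10L) + 1L] <- 5
  pol2 <- makeTrackFromVectors(rep(1, len), state = "expected")
  tef <- makeTrackFromVectors(pv + 1, state = "expected")
  rr <- nucleosomeRatios(tef, pol2, gene, list(chrI = 1100L),
                         scaling = c(X = 1), factor = "X")
  expect_equal(rr$ratio[rr$offset == 10L], (5 + 10) / 10)
  expect_true(all(abs(rr$ratio[rr$offset != 10L] - 1) < 1e-9))
})

test_that("flat TEF/Pol2 ratio gives a flat dyad-aligned profile", {
  genes <- metageneFixture(n_genes = 10L)
  dy <- integer(0)
  for (i in seq_len(nrow(genes))) {
    u <- seq(100L, 1800L, by = 165L)
    dy <- c(dy, if (genes$strand[i] == "+") genes$start[i] + u
               else genes$end[i] - 1L - u)
  }
  nucmap <- list(chrI = sort(dy))
  pol2 <- constantTrack(genes, 2)
  tef <- constantTrack(genes, 3)
  prof <- nucleosomeProfile(tef, pol2, genes, nucmap,
                            scaling = c(X = 4), factor = "X")
  expect_equal(length(profileOffsets(prof)), 20L)
  expect_true(all(abs(profileValues(prof) - 4 * 1.5) < 1e-9))
})

test_that("oscillation test matches the closed-form pooled t distribution", {
  set.seed(88)
  x <- rnorm(40); y <- rnorm(35, 0.3)
  got <- oscillationTest(x, y, alternative = "greater")
  oracle <- studentT(y, x)
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df, tolerance = 1e-10)
  expect_equal(got$p, pt(oracle$t, oracle$df, lower.tail = FALSE),
               tolerance = 1e-10)
  # no effect: identical constants give t = 0, p = 0.5 boundary behaviour
  same <- oscillationTest(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  # extreme shift is overwhelmingly significant
  shifted <- oscillationTest(rnorm(30), rnorm(30) + 10)
  expect_lt(shifted$p, 1e-6)
  # fewer than 3 values: undefined
  expect_true(is.na(oscillationTest(c(1, 2), rnorm(10))$p))
})

test_that("AUC normalization: identity, doubling, hand trapezoid", {
  mk <- function(v) new("BinnedProfile", offset = as.integer(seq(0, 90, 10)),
                        value = v, n = rep(5L, 10), anchor = "TSS",
                        bin = 10L, trim = 0.05)
  ref <- mk(c(1, 2, 4, 3, 2, 2, 2, 1, 1, 1))
  expect_equal(profileValues(aucNormalize(ref, ref, c(0, 100))),
               profileValues(ref))
  dbl <- mk(2 * c(1, 2, 4, 3, 2, 2, 2, 1, 1, 1))
  out <- aucNormalize(ref, dbl, c(0, 100))
  expect_equal(attr(out, "scale"), 0.5)
  expect_equal(profileValues(out), profileValues(ref))
  # hand trapezoid on centers 5..95: piecewise profiles
  q <- mk(c(2, 2, 2, 2, 2, 4, 4, 4, 4, 4))
  auc_ref <- sum(diff(seq(5, 95, 10)) *
                 (head(ref@value, -1) + tail(ref@value, -1)) / 2)
  auc_q <- sum(diff(seq(5, 95, 10)) *
               (head(q@value, -1) + tail(q@value, -1)) / 2)
  out <- aucNormalize(ref, q, c(0, 100))
  expect_equal(attr(out, "scale"), auc_ref / auc_q, tolerance = 1e-12)
  zero <- mk(rep(0, 10))
  expect_error(aucNormalize(ref, zero, c(0, 100)), "not positive")
})

test_that("heatmap rows are clamped, normalized and length-ordered", {
  # worked example: bin means (2, 0, -1, 3) -> (0.4, 0, 0, 0.6)
  len <- 200L
  v <- numeric(len)
  v[1:10] <- 2; v[11:20] <- 0; v[21:30] <- -1; v[31:40] <- 3
  tr <- makeTrackFromVectors(v, state = "background_subtracted")
  gene <- makeGene("g1", start = 0L, end = 40L)
  m <- heatmapMatrix(tr, gene)
  expect_equal(unname(m[1, ]), c(0.4, 0, 0, 0.6))
  # random tracks: rows sum to 1 or 0 exactly; matches a naive oracle
  set.seed(99)
  genes <- metageneFixture(n_genes = 8L, gene_len = 505L)
  genes$end <- genes$start + sample(c(200L, 505L, 1000L), 8, replace = TRUE)
  lenc <- genes$chrom_len[1]
  tr <- makeTrackFromVectors(as.numeric(rpois(lenc, 0.5)),
                             as.numeric(rpois(lenc, 0.5)))
  m <- heatmapMatrix(tr, genes)
  sums <- rowSums(m, na.rm = TRUE)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
  # rows ordered by gene length
  gl <- sort(genes$end - genes$start)
  expect_equal(unname(gl), unname((genes$end - genes$start)[
    match(rownames(m), genes$gene_id)]))
  # naive recomputation for one gene
  g <- genes[genes$gene_id == rownames(m)[nrow(m)], ]
  L <- g$end - g$start
  vv <- trackSignal(tr, "chrI", g$strand)
  pos <- if (g$strand == "+") g$start:(g$end - 1L) else (g$end - 1L):g$start
  x <- vv[pos + 1L]
  nb <- ceiling(L / 10)
  mu <- vapply(seq_len(nb), function(b) {
    idx <- ((b - 1L) * 10L + 1L):min(b * 10L, L)
    mean(x[idx])
  }, numeric(1))
  mu <- pmax(mu, 0)
  expect_equal(unname(m[nrow(m), seq_len(nb)]), mu / sum(mu),
               tolerance = 1e-12)
  # all-zero gene stays all-zero
  tz <- makeTrackFromVectors(numeric(200))
  mz <- heatmapMatrix(tz, makeGene("gz", start = 0L, end = 50L))
  expect_true(all(mz == 0))
})

test_that("profile smoothing is a centered running mean over bins", {
  p <- new("BinnedProfile", offset = as.integer(seq(0, 90, 10)),
           value = as.numeric(1:10), n = rep(3L, 10), anchor = "TSS",
           bin = 10L, trim = 0)
  sm <- smoothProfile(p, 5L)
  expect_equal(unname(profileValues(sm))[3:8], as.numeric(3:8))
  expect_equal(unname(profileValues(sm))[1], mean(1:3))
})
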