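# Shared fixture builders: everything is generated in code at test time.

# A one-chromosome track from explicit position/value pairs (0-based).
makeTrack <- function(len = 1000L, plus = NULL, minus = NULL,
                      chrom = "chrI", state = "raw_counts",
                      sample = "test") {
  vec <- function(spec) {
    v <- numeric(len)
    if (!is.null(spec)) v[spec$pos + 1L] <- spec$value
    v
  }
  strandedTrack(plus = stats::setNames(list(vec(plus)), chrom),
                minus = stats::setNames(list(vec(minus)), chrom),
                seqlengths = stats::setNames(len, chrom),
                sample = sample, state = state)
}

# A track with given full signal vectors.
makeTrackFromVectors <- function(plus_vec, minus_vec = NULL, chrom = "chrI",
                                 state = "raw_counts") {
  len <- length(plus_vec)
  if (is.null(minus_vec)) minus_vec <- numeric(len)
  strandedTrack(plus = stats::setNames(list(plus_vec), chrom),
                minus = stats::setNames(list(minus_vec), chrom),
                seqlengths = stats::setNames(len, chrom), state = state)
}

# Simple single-gene annotation row (0-based half-open).
makeGene <- function(gene_id = "g1", chrom = "chrI", strand = "+",
                     start = 0L, end = 100L, biotype = "mRNA") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end, biotype = biotype)
}

# Random gene set on one chromosome for brute-force comparisons.
randomGenes <- function(n, chrom_len = 100000L, chrom = "chrI") {
  tss <- sort(sample.int(chrom_len - 3000L, n))
  len <- sample(200:1500, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(0L, tss - len + 1L))
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             strand = strand, start = start, end = start + len,
             biotype = "mRNA")
}

# Brute-force divergent-pair enumerator (O(n^2)), independent of the
# implementation's sorted-successor shortcut.
bruteForcePairs <- function(genes, max_separation = 1200) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (genes$strand[i] != "-" || genes$strand[j] != "+") next
      if (genes$chrom[i] != genes$chrom[j]) next
      d <- tss[j] - tss[i]
      if (d <= 0 || d > max_separation) next
      blocked <- FALSE
      for (k in seq_len(nrow(genes))) {
        if (k == i || k == j) next
        if (genes$chrom[k] == genes$chrom[i] &&
            tss[k] > tss[i] && tss[k] < tss[j]) { blocked <- TRUE; break }
      }
      if (!blocked)
        out[[length(out) + 1L]] <- data.frame(gene1 = genes$gene_id[i],
                                              gene2 = genes$gene_id[j])
    }
  }
  if (length(out)) {
    x <- do.call(rbind, out)
    x[order(x$gene1, x$gene2), , drop = FALSE]
  } else data.frame(gene1 = character(), gene2 = character())
}

# Literal BH step-up oracle.
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Closed-form two-sample t statistics.
studentT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2)
}
welchT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  list(t = t, df = df)
}
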