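# Differential TEF-vs-Pol2 occupancy.
#
# Counting uses raw (unsubtracted) integer tracks because the NB model
# requires non-negative integers; background subtraction is reserved for
# profile statistics. The test is a self-contained median-of-ratios +
# method-of-moments dispersion (shrunk toward a mean-dispersion trend) +
# Wald scheme, so the pipeline carries no external statistical dependency.

#' Count gene-body 3'-end signal
#'
#' Sums the 3'-end counts on the gene's strand over the transcription-
#' direction interval `[TSS + start_offset, TES - end_offset)`, excluding the
#' regions near the gene ends where elongation factors show large transitions
#' in their association with Pol2. Genes whose trimmed interval is empty
#' (length <= start_offset + end_offset) are excluded and reported.
#'
#' @param track a raw-count [StrandedTrack-class].
#' @param genes annotation table.
#' @param start_offset nt skipped after the TSS (default 400).
#' @param end_offset nt skipped before the TES (default 200).
#' @return named integer vector of counts for eligible genes, with attribute
#'   `excluded` = gene ids of excluded genes.
#' @export
countGeneBody <- function(track, genes, start_offset = 400L,
                          end_offset = 200L) {
  validateAnnotations(genes)
  if (trackState(track) != "raw_counts")
    stop("gene-body counting requires a raw_counts track")
  genes <- genes[genes$chrom %in% names(seqlengths(track)), , drop = FALSE]
  len <- geneLength(genes)
  eligible <- len > start_offset + end_offset
  excluded <- genes$gene_id[!eligible]
  g <- genes[eligible, , drop = FALSE]
  tss <- geneTss(g)
  width <- geneLength(g) - start_offset - end_offset
  cums <- .trackCumsums(track)
  counts <- vapply(seq_len(nrow(g)), function(i) {
    .geneBinSums(cums, g$chrom[i], g$strand[i], tss[i] + 0L,
                 start_offset, width[i])
  }, numeric(1))
  out <- stats::setNames(as.integer(round(counts)), g$gene_id)
  attr(out, "excluded") <- excluded
  out
}

#' Build a genes x samples count table from several tracks
#'
#' @param tracks named list of raw-count [StrandedTrack-class] objects.
#' @param genes annotation table.
#' @param ... passed to [countGeneBody()].
#' @return integer matrix (genes common to all samples x samples).
#' @export
buildCountTable <- function(tracks, genes, ...) {
  cols <- lapply(tracks, countGeneBody, genes = genes, ...)
  ids <- Reduce(intersect, lapply(cols, names))
  mat <- vapply(cols, function(x) x[ids], numeric(length(ids)))
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  mat
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over genes with nonzero counts in every sample of
#' the ratio count / geometric-mean-across-samples.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @return named numeric vector of positive size factors.
#' @export
sizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no gene has nonzero counts in all samples; size factors cannot be ",
         "estimated - supply deeper libraries or fewer samples")
  loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2, function(cnts)
    exp(stats::median(log(cnts) - loggeo)))
  stats::setNames(sf, colnames(counts))
}

# Method-of-moments dispersion per gene, pooled over the two groups, with
# shrinkage toward a fitted a0 + a1/mu mean-dispersion trend in log space.
.estimateDispersions <- function(norm, grp, sf, shrink_weight,
                                 floor = 1e-8) {
  lv <- levels(grp)
  base_mean <- rowMeans(norm)
  num <- rep(0, nrow(norm)); den <- rep(0, nrow(norm))
  for (g in lv) {
    j <- which(grp == g)
    mug <- rowMeans(norm[, j, drop = FALSE])
    if (length(j) >= 2) {
      vg <- apply(norm[, j, drop = FALSE], 1, stats::var)
      cg <- mean(1 / sf[j])
      ag <- (vg - mug * cg) / mug^2
      ok <- is.finite(ag)
      num[ok] <- num[ok] + (length(j) - 1) * ag[ok]
      den[ok] <- den[ok] + (length(j) - 1)
    }
  }
  raw <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  # Trend alpha(mu) = a0 + a1/mu fitted by OLS on the raw moment estimates.
  # Raw estimates are unbiased but very noisy at few replicates, and may be
  # negative; keeping the negative values in the fit is what keeps the trend
  # itself unbiased.
  usable <- is.finite(raw) & base_mean > 0
  a0 <- if (any(usable)) max(mean(raw[usable]), floor) else 0.01
  a1 <- 0
  if (sum(usable) >= 10) {
    fit <- try(stats::lm(raw[usable] ~ I(1 / base_mean[usable])),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      if (all(is.finite(cf)) && cf[1] > 0 && cf[2] >= 0) {
        a0 <- cf[1]; a1 <- cf[2]
      }
    }
  }
  if (!is.finite(a0) || a0 <= 0) a0 <- 0.01
  trend <- pmax(a0 + a1 / pmax(base_mean, 1e-8), floor)
  # Linear-space shrinkage toward the trend; negative raw estimates are
  # truncated at zero only here, after the trend fit.
  w <- shrink_weight
  shrunk <- (1 - w) * pmax(raw, 0) + w * trend
  shrunk[!is.finite(shrunk)] <- trend[!is.finite(shrunk)]
  list(alpha = pmax(shrunk, floor), raw = raw, trend = trend,
       coef = c(a0 = unname(a0), a1 = unname(a1)))
}

#' Replicate-aware negative-binomial differential occupancy test
#'
#' For each gene, compares TEF-group and Pol2-group counts under a negative
#' binomial model (variance `mu + alpha * mu^2`): median-of-ratios
#' normalization, per-gene method-of-moments dispersion shrunk toward an
#' `a0 + a1/mu` mean-dispersion trend, and a Wald test of the log ratio of
#' group means. The log2 ratio is TEF relative to Pol2; when either group
#' mean is zero a pseudocount of 0.5 is added to both normalized means
#' (flagged in the output). P values are Benjamini-Hochberg adjusted and
#' genes are classified `enriched` / `depleted` / `ns` at `threshold_padj`.
#'
#' @param counts genes x samples matrix of non-negative integers.
#' @param groups factor (or character) of length `ncol(counts)` with two
#'   levels; the first level of `factor(groups, c("TEF","Pol2"))`-style
#'   ordering is taken as the numerator. Use the `numerator` argument to be
#'   explicit.
#' @param numerator group label treated as numerator of the ratio (default
#'   `"TEF"` if present, else the first level).
#' @param threshold_padj adjusted-p threshold for classification (default
#'   0.05).
#' @param shrink_weight weight of the trend in log-space dispersion
#'   shrinkage, in `[0, 1]` (default 0.8; few replicates warrant strong
#'   shrinkage).
#' @param pseudocount value added to both group means when either is zero
#'   (default 0.5).
#' @return data.frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2_ratio`, `lfc_se`, `stat`, `p`, `padj`, `class`,
#'   `pseudocount_used`, `dispersion`.
#' @export
nbDifferential <- function(counts, groups, numerator = NULL,
                           threshold_padj = 0.05, shrink_weight = 0.8,
                           pseudocount = 0.5) {
  counts <- as.matrix(counts)
  grp <- factor(groups)
  if (nlevels(grp) != 2)
    stop("exactly two groups are required")
  if (any(table(grp) < 2))
    stop("each group needs at least 2 replicates")
  if (is.null(numerator))
    numerator <- if ("TEF" %in% levels(grp)) "TEF" else levels(grp)[1]
  denom <- setdiff(levels(grp), numerator)
  sf <- sizeFactors(counts)
  norm <- sweep(counts, 2, sf, "/")
  jT <- which(grp == numerator); jP <- which(grp == denom)
  muT <- rowMeans(norm[, jT, drop = FALSE])
  muP <- rowMeans(norm[, jP, drop = FALSE])
  base_mean <- rowMeans(norm)
  disp <- .estimateDispersions(norm, grp, sf, shrink_weight)
  alpha <- disp$alpha

  pc_used <- muT == 0 | muP == 0
  muT_adj <- ifelse(pc_used, muT + pseudocount, muT)
  muP_adj <- ifelse(pc_used, muP + pseudocount, muP)
  log2_ratio <- log2(muT_adj / muP_adj)

  # Wald SE of log(muT/muP): Var(mean_j K_ij/s_j) = (1/m^2) sum_j
  # (mu/s_j + alpha mu^2), so Var(log mu_hat) ~ (1/m^2) sum_j (1/(mu s_j)
  # + alpha).
  vlog <- function(mu, j) {
    (1 / length(j)^2) * vapply(seq_along(mu), function(i)
      sum(1 / (mu[i] * sf[j]) + alpha[i]), numeric(1))
  }
  se_log <- sqrt(vlog(muT_adj, jT) + vlog(muP_adj, jP))
  stat <- log(muT_adj / muP_adj) / se_log
  p <- 2 * stats::pnorm(-abs(stat))
  p[!is.finite(stat)] <- NA_real_
  padj <- stats::p.adjust(p, method = "BH")
  class <- rep("ns", length(p))
  class[!is.na(padj) & padj < threshold_padj & log2_ratio > 0] <- "enriched"
  class[!is.na(padj) & padj < threshold_padj & log2_ratio < 0] <- "depleted"

  out <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2_ratio = log2_ratio, lfc_se = se_log / log(2),
                    stat = stat, p = p, padj = padj, class = class,
                    pseudocount_used = pc_used, dispersion = alpha)
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "dispersion_trend") <- disp$coef
  out
}

#' Select gene groups from a differential result
#'
#' @param results data.frame from [nbDifferential()].
#' @param rule `"padj_threshold"` (default) or `"top_k_by_log2"`.
#' @param padj adjusted-p cutoff for the threshold rule (default 0.05).
#' @param k group size for the top-k rule.
#' @return list with character vectors `enriched` and `depleted`; for the
#'   top-k rule these are the k highest and k lowest genes by `log2_ratio`
#'   (ties broken by gene id).
#' @export
selectGroups <- function(results, rule = c("padj_threshold", "top_k_by_log2"),
                         padj = 0.05, k = NULL) {
  rule <- match.arg(rule)
  if (rule == "padj_threshold") {
    sig <- !is.na(results$padj) & results$padj < padj
    list(enriched = results$gene_id[sig & results$log2_ratio > 0],
         depleted = results$gene_id[sig & results$log2_ratio < 0])
  } else {
    if (is.null(k)) stop("the top-k rule requires k")
    if (k > nrow(results))
      stop("k exceeds the number of genes (", nrow(results), ")")
    o <- order(-results$log2_ratio, results$gene_id)
    list(enriched = results$gene_id[o[seq_len(k)]],
         depleted = results$gene_id[rev(o)[seq_len(k)]])
  }
}

#' Write/read a count table or differential results as TSV
#'
#' @param x matrix (counts) or data.frame (results).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  utils::write.table(data.frame(gene_id = rownames(x), x,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  storage.mode(m) <- "integer"
  m
}

#' @rdname writeCountTable
#' @param results differential result data.frame.
#' @export
writeDifferentialResults <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
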