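# Anchor-aligned metagene profiles with trimmed means.
#
# Bin bookkeeping: the anchor (TSS, PAS or nucleosome dyad center) sits on a
# bin edge, bins are labelled by the transcription-direction offset of their
# 5' edge, and minus-strand genes are orientation-flipped so "downstream"
# always means the direction of transcription.

#' Factor-specific scaling constants for Pol2-normalized profiles
#'
#' Scaling factors that bring TEF/Pol2 ratio profiles for different
#' immunoprecipitated factors onto one arbitrary linear scale, compensating
#' for sequencing depth and IP efficiency differences.
#'
#' @return named numeric vector of per-factor scalings.
#' @export
defaultFactorScaling <- function() {
  c(Cet1 = 1, Paf1 = 2.2, Pcf11 = 2.7, Spt6 = 0.47, Spt16 = 1.04,
    Set2 = 6, Ssu72 = 8)
}

#' Scaling constants for Rpb2-normalized Paf1 profiles
#'
#' @return named numeric vector: `single_ip` (0.88) and `sequential_ip`
#'   (0.75), the constants applied to Paf1/Rpb2 ratios for single and
#'   sequential IP data respectively.
#' @export
rpb2NormalizationConstants <- function() {
  c(single_ip = 0.88, sequential_ip = 0.75)
}

#' Trimmed mean with deterministic floor-count trimming
#'
#' Removes exactly `floor(trim * n)` values from each tail of the sorted
#' sample before averaging, so the trim count is deterministic. With
#' `trim = 0` this is the plain mean, and for constant samples the trimmed
#' and untrimmed means coincide.
#'
#' @param x numeric values (NAs removed first).
#' @param trim fraction trimmed per tail, in `[0, 0.5)`.
#' @return the trimmed mean (NA for an empty sample).
#' @examples
#' trimmedMean(1:20, 0.05)  # drops 1 and 20 -> 10.5
#' @export
trimmedMean <- function(x, trim) {
  stopifnot(trim >= 0, trim < 0.5)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  k <- floor(trim * n)
  if (2 * k >= n) return(NA_real_)
  mean(sort(x)[(k + 1):(n - k)])
}

#' @rdname trimmedMean
#' @return `trimValues`: the retained (post-trim) values, sorted.
#' @export
trimValues <- function(x, trim) {
  stopifnot(trim >= 0, trim < 0.5)
  x <- x[!is.na(x)]
  n <- length(x)
  k <- floor(trim * n)
  if (n == 0 || 2 * k >= n) return(numeric())
  sort(x)[(k + 1):(n - k)]
}

# Per-chromosome/strand cumulative sums for fast bin sums.
.trackCumsums <- function(track) {
  sl <- seqlengths(track)
  out <- list()
  for (ch in names(sl)) {
    out[[paste0(ch, "+")]] <- c(0, cumsum(trackSignal(track, ch, "+")))
    out[[paste0(ch, "-")]] <- c(0, cumsum(trackSignal(track, ch, "-")))
  }
  attr(out, "seqlengths") <- sl
  out
}

# Bin sums for one gene: bins with 5'-edge transcription-direction offsets
# `offsets` relative to genomic anchor position `anchor`. Out-of-chromosome
# bins are NA.
.geneBinSums <- function(cums, chrom, strand, anchor, offsets, bin) {
  S <- cums[[paste0(chrom, strand)]]
  n <- length(S) - 1L
  if (strand == "+") {
    s <- anchor + offsets            # genomic bin starts, 0-based
    e <- s + bin                     # half-open ends
  } else {
    e <- anchor - offsets + 1L
    s <- e - bin
  }
  ok <- s >= 0L & e <= n
  out <- rep(NA_real_, length(offsets))
  out[ok] <- S[e[ok] + 1L] - S[s[ok] + 1L]
  out
}

# genes x bins matrix of per-gene bin sums with the anchor-specific
# exclusions applied as NA. Whole bins are dropped if any part lies in an
# excluded zone.
.binSumMatrix <- function(track, genes, anchor, offsets, bin) {
  validateAnnotations(genes)
  cums <- .trackCumsums(track)
  known <- genes$chrom %in% names(seqlengths(track))
  if (!all(known)) {
    warning(sum(!known), " gene(s) on unknown chromosomes were excluded")
    genes <- genes[known, , drop = FALSE]
  }
  tss <- geneTss(genes); len <- geneLength(genes)
  if (anchor == "PAS") {
    keep <- len > 500L               # genes shorter than 501 nt excluded
    genes <- genes[keep, , drop = FALSE]
    tss <- tss[keep]; len <- len[keep]
  }
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(offsets),
              dimnames = list(genes$gene_id, offsets))
  for (i in seq_len(nrow(genes))) {
    a <- if (anchor == "TSS") tss[i] else geneTes(genes)[i]
    v <- .geneBinSums(cums, genes$chrom[i], genes$strand[i], a, offsets, bin)
    if (anchor == "TSS") {
      # exclusion zone: everything from gene coordinate L-200 onwards
      v[offsets + bin - 1L >= len[i] - 200L] <- NA_real_
    } else {
      # exclusion zone: everything up to gene coordinate 500 (TSS..TSS+500)
      v[offsets < 501L - len[i]] <- NA_real_
    }
    m[i, ] <- v
  }
  m
}

.profileFromMatrix <- function(m, offsets, anchor, bin, trim) {
  value <- apply(m, 2, trimmedMean, trim = trim)
  n <- apply(m, 2, function(x) sum(!is.na(x)))
  new("BinnedProfile", offset = as.integer(offsets), value = as.numeric(value),
      n = as.integer(n), anchor = anchor, bin = as.integer(bin),
      trim = trim)
}

.anchorWindow <- function(anchor, upstream, downstream, bin) {
  if (is.null(upstream)) upstream <- if (anchor == "TSS") 100L else 400L
  if (is.null(downstream)) downstream <- if (anchor == "TSS") 1000L else 100L
  if (upstream %% bin != 0 || downstream %% bin != 0)
    stop("window bounds must be multiples of the bin width")
  seq.int(-upstream, downstream - bin, by = bin)
}

#' Standard average occupancy profile
#'
#' Anchor-aligned metagene profile of per-bin counts: for each 10-nt bin of
#' the window the per-gene counts are collected and summarized by a trimmed
#' mean (default 5% per tail), preventing highly and lowly transcribed genes
#' from skewing the average. TSS-anchored profiles span TSS-100..TSS+1000 and
#' exclude, per gene, all bins from 200 nt upstream of that gene's PAS
#' onwards; PAS-anchored profiles span PAS-400..PAS+100, exclude genes of
#' 500 nt or shorter and, per gene, all bins within the first 500 nt after
#' the TSS. Bins are dropped whole if any part lies in an excluded zone, and
#' bins with no eligible gene are reported as missing, not zero.
#'
#' @param track a [StrandedTrack-class] (unsmoothed).
#' @param genes annotation table of the genes to average.
#' @param anchor `"TSS"` or `"PAS"`.
#' @param upstream,downstream window half-widths in nt (multiples of `bin`);
#'   defaults 100/1000 for TSS, 400/100 for PAS.
#' @param bin bin width in nt (default 10).
#' @param trim trim fraction per tail (default 0.05).
#' @return a [BinnedProfile-class].
#' @export
standardProfile <- function(track, genes, anchor = c("TSS", "PAS"),
                            upstream = NULL, downstream = NULL, bin = 10L,
                            trim = 0.05) {
  anchor <- match.arg(anchor)
  offsets <- .anchorWindow(anchor, upstream, downstream, bin)
  m <- .binSumMatrix(track, genes, anchor, offsets, bin)
  .profileFromMatrix(m, offsets, anchor, bin, trim)
}

#' Pol2-normalized TEF occupancy profile
#'
#' For each gene and bin the ratio `(scaling[factor] * TEF counts) / (Pol2
#' counts)` is formed; ratios with non-positive Pol2 bin counts are undefined
#' and dropped, and the per-bin summary is a trimmed mean with 10% trimmed
#' per tail (guarding against single-nucleotide spikes). Anchors, windows and
#' per-gene exclusions are as in [standardProfile()].
#'
#' @inheritParams standardProfile
#' @param tef TEF-seq [StrandedTrack-class].
#' @param pol2 NET-seq (Pol2) [StrandedTrack-class].
#' @param scaling named numeric vector of factor scalings
#'   (default [defaultFactorScaling()]).
#' @param factor factor name to look up in `scaling`.
#' @param trim trim fraction per tail (default 0.10).
#' @return a [BinnedProfile-class] of mean scaled TEF/Pol2 ratios.
#' @export
ratioProfile <- function(tef, pol2, genes, anchor = c("TSS", "PAS"),
                         upstream = NULL, downstream = NULL, bin = 10L,
                         trim = 0.10, scaling = defaultFactorScaling(),
                         factor = "Paf1") {
  anchor <- match.arg(anchor)
  s <- .lookupScaling(scaling, factor)
  .checkSameGenome(tef, pol2)
  offsets <- .anchorWindow(anchor, upstream, downstream, bin)
  mt <- .binSumMatrix(tef, genes, anchor, offsets, bin)
  mp <- .binSumMatrix(pol2, genes, anchor, offsets, bin)
  r <- s * mt / mp
  r[!is.na(mp) & mp <= 0] <- NA_real_
  .profileFromMatrix(r, offsets, anchor, bin, trim)
}

.lookupScaling <- function(scaling, factor) {
  if (!factor %in% names(scaling))
    stop("no scaling factor for '", factor, "'; known: ",
         paste(names(scaling), collapse = ", "))
  s <- scaling[[factor]]
  if (!is.finite(s) || s <= 0) stop("scaling factors must be positive")
  s
}

#' Read a nucleosome dyad-center map
#'
#' @param path two-column TSV (`chrom`, `pos`, header, 1-based dyad centers)
#'   or 3+-column headerless BED (dyad = interval midpoint, 0-based).
#' @param format `"tsv"` or `"bed"`.
#' @return named list of sorted 0-based dyad positions per chromosome.
#' @export
readNucleosomeMap <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    pos <- as.integer(x$pos) - 1L
    chrom <- x$chrom
  } else {
    x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    chrom <- x[[1]]
    pos <- as.integer(floor((x[[2]] + x[[3]] - 1L) / 2))
  }
  out <- lapply(split(pos, chrom), function(p) sort(unique(p)))
  out
}

#' Nucleosome dyad instances within genes
#'
#' Enumerates, for each gene, the dyads lying strictly after TSS+50 nt and
#' strictly before the PAS, with their ordinal (+1, +2, ...) counted over all
#' dyads downstream of the TSS within the gene.
#'
#' @param genes annotation table.
#' @param nucmap named list of sorted 0-based dyad positions per chromosome
#'   (see [readNucleosomeMap()]).
#' @param ordinals optional integer vector restricting to given nucleosome
#'   ordinals (e.g. `2:5`).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `dyad`
#'   (genomic 0-based), `ordinal`, `u` (transcription-direction offset of the
#'   dyad from the TSS).
#' @export
nucleosomeInstances <- function(genes, nucmap, ordinals = NULL) {
  validateAnnotations(genes)
  tss <- geneTss(genes); len <- geneLength(genes)
  res <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    d <- nucmap[[genes$chrom[i]]]
    if (is.null(d) || length(d) == 0) next
    u <- if (genes$strand[i] == "+") d - tss[i] else tss[i] - d
    inside <- which(u > 0 & u < len[i])
    if (!length(inside)) next
    o <- inside[order(u[inside])]
    ord <- seq_along(o)
    keep <- u[o] > 50L & u[o] < len[i] - 1L
    if (!is.null(ordinals)) keep <- keep & ord %in% ordinals
    if (!any(keep)) next
    res[[i]] <- data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                           strand = genes$strand[i], dyad = d[o[keep]],
                           ordinal = ord[keep], u = u[o[keep]])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), dyad = integer(),
                      ordinal = integer(), u = integer())
  rownames(out) <- NULL
  out
}

#' Per-instance scaled TEF/Pol2 ratios around nucleosome dyads
#'
#' Each qualifying (gene, dyad) instance contributes one window of
#' `flank` nt either side of the dyad, split into `bin`-nt bins
#' (orientation-flipped for minus-strand genes). Ratios with non-positive
#' Pol2 bin counts are dropped.
#'
#' @inheritParams ratioProfile
#' @param nucmap dyad map (see [readNucleosomeMap()]).
#' @param flank half-window around each dyad in nt (default 100).
#' @param ordinals optional nucleosome ordinals to keep (e.g. `2:5`).
#' @return data.frame with columns `gene_id`, `ordinal`, `offset` (bin
#'   5'-edge offset from the dyad) and `ratio`.
#' @export
nucleosomeRatios <- function(tef, pol2, genes, nucmap, flank = 100L,
                             bin = 10L, scaling = defaultFactorScaling(),
                             factor = "Paf1", ordinals = NULL) {
  s <- .lookupScaling(scaling, factor)
  .checkSameGenome(tef, pol2)
  inst <- nucleosomeInstances(genes, nucmap, ordinals)
  offsets <- seq.int(-flank, flank - bin, by = bin)
  ct <- .trackCumsums(tef); cp <- .trackCumsums(pol2)
  res <- vector("list", nrow(inst))
  for (k in seq_len(nrow(inst))) {
    vt <- .geneBinSums(ct, inst$chrom[k], inst$strand[k], inst$dyad[k],
                       offsets, bin)
    vp <- .geneBinSums(cp, inst$chrom[k], inst$strand[k], inst$dyad[k],
                       offsets, bin)
    r <- s * vt / vp
    r[is.na(vp) | vp <= 0] <- NA_real_
    ok <- !is.na(r)
    if (!any(ok)) next
    res[[k]] <- data.frame(gene_id = inst$gene_id[k],
                           ordinal = inst$ordinal[k],
                           offset = offsets[ok], ratio = r[ok])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), ordinal = integer(),
                      offset = integer(), ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Nucleosome-dyad-aligned Pol2-normalized TEF profile
#'
#' Trimmed-mean (10% per tail) of the per-instance scaled TEF/Pol2 ratios of
#' [nucleosomeRatios()], per bin of the dyad-aligned grid.
#'
#' @inheritParams nucleosomeRatios
#' @param trim trim fraction per tail (default 0.10).
#' @return a [BinnedProfile-class] anchored at `"nucleosome_center"`.
#' @export
nucleosomeProfile <- function(tef, pol2, genes, nucmap, flank = 100L,
                              bin = 10L, trim = 0.10,
                              scaling = defaultFactorScaling(),
                              factor = "Paf1", ordinals = NULL) {
  rr <- nucleosomeRatios(tef, pol2, genes, nucmap, flank, bin, scaling,
                         factor, ordinals)
  offsets <- seq.int(-flank, flank - bin, by = bin)
  value <- n <- rep(NA_real_, length(offsets))
  for (j in seq_along(offsets)) {
    x <- rr$ratio[rr$offset == offsets[j]]
    value[j] <- trimmedMean(x, trim)
    n[j] <- length(x)
  }
  new("BinnedProfile", offset = as.integer(offsets), value = value,
      n = as.integer(n), anchor = "nucleosome_center", bin = as.integer(bin),
      trim = trim)
}

#' One-tailed two-sample t test for dyad-phased oscillation
#'
#' Tests whether the mean TEF/Pol2 ratio at the dyad center + 50 nt exceeds
#' the mean at the dyad center (direction configurable), on the retained
#' (post-trim) per-instance ratios at the two bins.
#'
#' @param center per-instance ratios at the dyad-center bin.
#' @param shifted per-instance ratios at the center+50 nt bin.
#' @param alternative `"greater"` (default: mean(shifted) > mean(center)) or
#'   `"less"`.
#' @param var_equal pooled-variance Student test if TRUE (default), Welch
#'   otherwise.
#' @param paired pair instances (requires equal lengths).
#' @return list with elements `t`, `df`, `p`, `n_center`, `n_shifted`; all
#'   statistics NA when either sample has fewer than 3 values.
#' @export
oscillationTest <- function(center, shifted,
                            alternative = c("greater", "less"),
                            var_equal = TRUE, paired = FALSE) {
  alternative <- match.arg(alternative)
  center <- center[!is.na(center)]; shifted <- shifted[!is.na(shifted)]
  if (length(center) < 3 || length(shifted) < 3)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                n_center = length(center), n_shifted = length(shifted)))
  ht <- stats::t.test(shifted, center, alternative = alternative,
                      var.equal = var_equal, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), n_center = length(center),
       n_shifted = length(shifted))
}

#' Per-ordinal oscillation tests on nucleosome-phased ratios
#'
#' For each nucleosome ordinal, extracts the per-instance ratios at the
#' dyad-center bin and at the center+`shift` bin, trims each sample and runs
#' [oscillationTest()].
#'
#' @inheritParams nucleosomeRatios
#' @param ordinals nucleosome ordinals to test (default `2:5`).
#' @param shift offset of the comparison bin from the center bin in nt
#'   (default 50).
#' @param trim trim fraction per tail applied to each sample (default 0.10).
#' @param alternative passed to [oscillationTest()].
#' @param paired pair the two bins by instance (same gene and dyad) and run
#'   a one-sample Yuen test (trimmed mean over winsorized-variance SE) on the
#'   within-instance differences; the unpaired two-sample Student test on
#'   trimmed ratios is the default. Pairing removes the shared per-instance
#'   component of the two bins (gene-level enrichment, local phase), and the
#'   winsorized SE keeps the trimmed statistic calibrated under the null.
#' @return data.frame with one row per ordinal: `ordinal`, `t`, `df`, `p`,
#'   `n_center`, `n_shifted`.
#' @export
oscillationTestByOrdinal <- function(tef, pol2, genes, nucmap,
                                     ordinals = 2:5, shift = 50L,
                                     flank = 100L, bin = 10L, trim = 0.10,
                                     scaling = defaultFactorScaling(),
                                     factor = "Paf1",
                                     alternative = "greater",
                                     paired = FALSE) {
  alternative <- match.arg(alternative, c("greater", "less"))
  rr <- nucleosomeRatios(tef, pol2, genes, nucmap, flank, bin, scaling,
                         factor, ordinals)
  out <- lapply(ordinals, function(o) {
    xi <- rr[rr$ordinal == o & rr$offset == 0L, ]
    yi <- rr[rr$ordinal == o & rr$offset == shift, ]
    if (paired) {
      ids <- intersect(xi$gene_id, yi$gene_id)
      d <- yi$ratio[match(ids, yi$gene_id)] - xi$ratio[match(ids, xi$gene_id)]
      d <- d[!is.na(d)]
      if (length(d) < 3 || length(trimValues(d, trim)) < 3)
        return(data.frame(ordinal = o, t = NA_real_, df = NA_real_,
                          p = NA_real_, n_center = length(d),
                          n_shifted = length(d)))
      yt <- .yuenOneSample(d, trim)
      pval <- if (alternative == "greater")
        stats::pt(yt$t, yt$df, lower.tail = FALSE)
      else stats::pt(yt$t, yt$df)
      data.frame(ordinal = o, t = yt$t, df = yt$df, p = pval,
                 n_center = length(d), n_shifted = length(d))
    } else {
      x <- trimValues(xi$ratio, trim)
      y <- trimValues(yi$ratio, trim)
      tt <- oscillationTest(x, y, alternative = alternative)
      data.frame(ordinal = o, t = tt$t, df = tt$df, p = tt$p,
                 n_center = tt$n_center, n_shifted = tt$n_shifted)
    }
  })
  do.call(rbind, out)
}

# One-sample Yuen test: trimmed mean with winsorized-variance standard
# error. The sample SD of a trimmed sample underestimates the SE of the
# trimmed mean, so a plain t on trimmed values is anticonservative; the
# winsorized variance is the correct scale. With trim = 0 this is the
# ordinary one-sample t.
.yuenOneSample <- function(x, trim) {
  n <- length(x)
  k <- floor(trim * n)
  s <- sort(x)
  tm <- mean(s[(k + 1):(n - k)])
  w <- s
  if (k > 0) {
    w[1:k] <- s[k + 1]
    w[(n - k + 1):n] <- s[n - k]
  }
  h <- n - 2 * k
  se <- sqrt(stats::var(w) * (n - 1) / (h * (h - 1)))
  list(t = tm / se, df = h - 1)
}

#' Scale one profile so its AUC over a span matches a reference
#'
#' Computes the trapezoidal area under each profile over `span` (bin-center
#' coordinates) and rescales the query by `AUC(reference) / AUC(query)`; the
#' reference is untouched. Used to overlay profiles from libraries of
#' different depth.
#'
#' @param reference,query [BinnedProfile-class] objects on the same bin grid.
#' @param span numeric length-2: offset range (e.g. `c(0, 2000)` for
#'   TSS..PAS on a TSS-anchored grid).
#' @return the rescaled query profile; the applied scale is stored in
#'   attribute `"scale"`.
#' @export
aucNormalize <- function(reference, query, span) {
  if (!identical(profileOffsets(reference), profileOffsets(query)))
    stop("profiles do not share a bin grid")
  sel <- reference@offset >= span[1] & reference@offset + reference@bin <= span[2]
  if (sum(sel) < 2) stop("span covers fewer than 2 bins")
  ctr <- reference@offset[sel] + reference@bin / 2
  okr <- !is.na(reference@value[sel]); okq <- !is.na(query@value[sel])
  auc_ref <- pracma::trapz(ctr[okr], reference@value[sel][okr])
  auc_qry <- pracma::trapz(ctr[okq], query@value[sel][okq])
  if (!is.finite(auc_qry) || auc_qry <= 0)
    stop("query AUC over the span is not positive; cannot normalize")
  sc <- auc_ref / auc_qry
  out <- new("BinnedProfile", offset = query@offset,
             value = query@value * sc, n = query@n, anchor = query@anchor,
             bin = query@bin, trim = query@trim)
  attr(out, "scale") <- sc
  out
}

#' Running-mean smoothing of a profile (presentation layer)
#'
#' Centered running mean over `bins` consecutive bins of an already-computed
#' profile, for display only.
#'
#' @param profile a [BinnedProfile-class].
#' @param bins odd number of bins in the moving window (default 5).
#' @return a smoothed [BinnedProfile-class].
#' @export
smoothProfile <- function(profile, bins = 5L) {
  if (bins %% 2L != 1L || bins < 1L) stop("bins must be odd and >= 1")
  h <- (bins - 1L) %/% 2L
  v <- profile@value
  sm <- vapply(seq_along(v), function(i) {
    w <- v[max(1L, i - h):min(length(v), i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  new("BinnedProfile", offset = profile@offset, value = sm, n = profile@n,
      anchor = profile@anchor, bin = profile@bin, trim = profile@trim)
}

#' Length-ordered row-normalized heatmap matrix
#'
#' Per gene, the track is split into `bin`-nt bins over the gene body
#' (TSS..TES, transcription direction), per-bin mean counts are computed,
#' negatives are replaced with zero, and the row is divided by its total so
#' it sums to 1 (all-zero rows stay all-zero). Rows are ordered by increasing
#' gene length; columns beyond a gene's end are NA.
#'
#' @param track a [StrandedTrack-class] (may be background-subtracted).
#' @param genes annotation table.
#' @param bin bin width in nt (default 10).
#' @return numeric matrix, rownames = gene ids.
#' @export
heatmapMatrix <- function(track, genes, bin = 10L) {
  validateAnnotations(genes)
  genes <- genes[genes$chrom %in% names(seqlengths(track)), , drop = FALSE]
  len <- geneLength(genes)
  genes <- genes[order(len, genes$gene_id), , drop = FALSE]
  len <- geneLength(genes)
  tss <- geneTss(genes)
  cums <- .trackCumsums(track)
  ncol_max <- max(ceiling(len / bin))
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_max,
              dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    nb <- ceiling(len[i] / bin)
    offsets <- (seq_len(nb) - 1L) * bin
    v <- .geneBinSums(cums, genes$chrom[i], genes$strand[i], tss[i],
                      offsets, bin)
    w <- rep(bin, nb)
    if (len[i] %% bin != 0) {
      # last bin is partial: recompute its sum over the true width
      w[nb] <- len[i] - (nb - 1L) * bin
      vlast <- .geneBinSums(cums, genes$chrom[i], genes$strand[i], tss[i],
                            offsets[nb], w[nb])
      v[nb] <- vlast
    }
    mu <- pmax(v / w, 0)
    tot <- sum(mu, na.rm = TRUE)
    m[i, seq_len(nb)] <- if (tot > 0) mu / tot else mu
  }
  m
}

#' Write a profile or heatmap matrix as TSV
#'
#' @param x a [BinnedProfile-class] or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(x, path) {
  if (is(x, "BinnedProfile")) x <- as.data.frame(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = is.matrix(x))
  invisible(path)
}
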