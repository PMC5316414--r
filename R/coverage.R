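# Strand-specific single-nucleotide 3'-end coverage.

#' Narrow aligned reads to their 3' nucleotide
#'
#' Converts aligned reads into a strand-specific single-nucleotide track where
#' each retained read contributes exactly +1 at one position, so total track
#' mass equals the number of retained reads.
#'
#' In `"as_aligned"` mode (the default) a read is counted at the 3'-most
#' aligned position on its alignment strand: the last covered base for a
#' plus-strand alignment, the first covered base for a minus-strand
#' alignment. In `"reverse_complement"` mode, for library chemistries where
#' the nascent-RNA 3' end is the read's 5' base on the opposite strand, the
#' read is counted at its 5'-most aligned base and assigned to the opposite
#' strand.
#'
#' @param reads either a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open alignment span) and `strand`, or the path to a BAM or
#'   SAM file (SAM files are converted with [Rsamtools::asBam()]; secondary
#'   and unmapped alignments are dropped, and uniqueness of mapping is the
#'   upstream aligner's responsibility).
#' @param seqlengths named integer vector of chromosome lengths.
#' @param orientation_mode `"as_aligned"` or `"reverse_complement"`.
#' @param sample sample id stored in the track.
#' @return a [StrandedTrack-class] in state `"raw_counts"`, with attribute
#'   `skipped` = number of reads dropped for lying on unknown chromosomes.
#' @examples
#' sl <- c(chrI = 200L)
#' rd <- data.frame(chrom = "chrI", start = 100, end = 150, strand = "+")
#' tr <- narrowTo3Prime(rd, sl)
#' trackSignal(tr, "chrI", "+")[150]  # position 149 (0-based) holds the read
#' @export
narrowTo3Prime <- function(reads, seqlengths,
                           orientation_mode = c("as_aligned",
                                                "reverse_complement"),
                           sample = "sample") {
  orientation_mode <- match.arg(orientation_mode)
  if (is.character(reads) && length(reads) == 1L)
    reads <- readAlignedReads(reads)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) && any(reads$end <= reads$start))
    stop("read alignment spans must be non-empty")
  known <- reads$chrom %in% names(seqlengths)
  skipped <- sum(!known)
  if (skipped)
    warning(skipped, " read(s) on unknown chromosomes were skipped")
  reads <- reads[known, , drop = FALSE]

  if (orientation_mode == "as_aligned") {
    pos <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
    str_out <- reads$strand
  } else {
    pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
    str_out <- ifelse(reads$strand == "+", "-", "+")
  }

  mk <- function(sel) {
    out <- list()
    for (ch in names(seqlengths)) {
      idx <- sel & reads$chrom == ch
      out[[ch]] <- as.numeric(tabulate(pos[idx] + 1L,
                                       nbins = seqlengths[[ch]]))
    }
    out
  }
  tr <- strandedTrack(plus = mk(str_out == "+"), minus = mk(str_out == "-"),
                      seqlengths = seqlengths, sample = sample,
                      state = "raw_counts")
  attr(tr, "skipped") <- skipped
  tr
}

#' Read primary alignments from a BAM/SAM file as a read table
#'
#' @param path BAM or SAM file. SAM input is converted to BAM in a temporary
#'   location first.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `strand`.
#' @export
readAlignedReads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags))
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)))
}

# Per-(chrom, strand) window cut points from gene annotations. A cut at
# coordinate k forbids any window from covering both positions k-1 and k.
# Cuts fall immediately 5' of each TSS and immediately 3' of each TES, exon
# 3' nt and intron 3' nt (all in transcription direction).
.boundaryCuts <- function(genes, chrom, strand) {
  g <- genes[genes$chrom == chrom & genes$strand == strand, , drop = FALSE]
  if (nrow(g) == 0) return(integer())
  tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  after3 <- function(p) if (strand == "+") p + 1L else p  # cut 3' of base p
  cuts <- c(if (strand == "+") tss else tss + 1L, after3(tes))
  if (!is.null(g$intron_bounds)) {
    for (b in g$intron_bounds) {
      if (is.null(b) || nrow(b) == 0) next
      cuts <- c(cuts, after3(b$exon3), after3(b$intron3))
    }
  }
  sort(unique(as.integer(cuts)))
}

.truncatedRunningMean <- function(x, cuts, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n) - 1L                      # 0-based positions
  cuts <- cuts[cuts > 0L & cuts < n]        # chromosome ends are implicit
  S <- c(0, cumsum(x))
  if (length(cuts) == 0L) {
    lo <- pmax(i - h, 0L)
    hi <- pmin(i + h, n - 1L)
  } else {
    idx <- findInterval(i, cuts)            # cuts[idx] <= i (0 if none)
    lo <- pmax(i - h, c(0L, cuts)[idx + 1L])
    hi <- pmin(i + h, c(cuts, n)[idx + 1L] - 1L)
  }
  (S[hi + 2L] - S[lo + 1L]) / (hi - lo + 1L)
}

#' Boundary-aware running mean for visualization tracks
#'
#' Smooths each strand of a track with a centered running mean whose window
#' shrinks so that it never spans a forbidden boundary: a gene TSS, TES, the
#' 3' nt of an exon upstream of an intron, or the 3' nt of an intron, for
#' genes on the same strand. Smoothed tracks are a terminal visualization
#' product: quantitative operations (profiles, counting, testing) always use
#' unsmoothed tracks.
#'
#' @param track a [StrandedTrack-class].
#' @param genes annotation table supplying the boundaries.
#' @param window odd window width in nt (default 11).
#' @return a [StrandedTrack-class] in state `"smoothed"`.
#' @export
boundaryAwareRunningMean <- function(track, genes, window = 11L) {
  if (window %% 2L != 1L || window < 1L)
    stop("window must be odd and >= 1")
  validateAnnotations(genes)
  sl <- seqlengths(track)
  sm <- function(strand) {
    out <- list()
    for (ch in names(sl)) {
      cuts <- .boundaryCuts(genes, ch, strand)
      out[[ch]] <- .truncatedRunningMean(trackSignal(track, ch, strand),
                                         cuts, as.integer(window))
    }
    out
  }
  strandedTrack(plus = sm("+"), minus = sm("-"), seqlengths = sl,
                sample = track@sample, state = "smoothed")
}

# ---- bedGraph I/O ----
# Plain 4-column bedGraph, 0-based half-open, one file per strand. Runs of
# equal signal are collapsed; zero runs are omitted. Values are written with
# 17 significant digits so integer tracks round-trip bit-identically.

.writeBedGraphStrand <- function(vlist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(vlist)) {
    v <- vlist[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.17g", ch, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Write/read a StrandedTrack as a pair of bedGraph files
#'
#' Writes `<prefix>.plus.bedGraph` and `<prefix>.minus.bedGraph` (0-based
#' half-open, zero runs omitted). Integer tracks round-trip bit-identically.
#'
#' @param track a [StrandedTrack-class].
#' @param prefix output path prefix.
#' @return `writeTrackBedGraph`: the two paths, invisibly.
#'   `readTrackBedGraph`: the reconstructed [StrandedTrack-class].
#' @export
writeTrackBedGraph <- function(track, prefix) {
  p <- paste0(prefix, ".plus.bedGraph")
  m <- paste0(prefix, ".minus.bedGraph")
  .writeBedGraphStrand(track@plus, p)
  .writeBedGraphStrand(track@minus, m)
  invisible(c(plus = p, minus = m))
}

.readBedGraphStrand <- function(path, seqlengths) {
  out <- lapply(seqlengths, numeric)
  if (file.exists(path) && file.size(path) > 0) {
    x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
    for (ch in unique(x$chrom)) {
      if (!ch %in% names(seqlengths))
        stop("bedGraph chromosome not in seqlengths: ", ch)
      xi <- x[x$chrom == ch, ]
      for (k in seq_len(nrow(xi)))
        out[[ch]][(xi$start[k] + 1L):xi$end[k]] <- xi$value[k]
    }
  }
  out
}

#' @rdname writeTrackBedGraph
#' @param seqlengths named integer vector of chromosome lengths.
#' @param sample,state metadata for the reconstructed track.
#' @export
readTrackBedGraph <- function(prefix, seqlengths, sample = "sample",
                              state = "raw_counts") {
  strandedTrack(
    plus = .readBedGraphStrand(paste0(prefix, ".plus.bedGraph"), seqlengths),
    minus = .readBedGraphStrand(paste0(prefix, ".minus.bedGraph"), seqlengths),
    seqlengths = seqlengths, sample = sample, state = state)
}
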