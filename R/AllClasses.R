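#' @import methods
#' @importFrom GenomeInfoDb seqlengths
NULL

.TRACK_STATES <- c("raw_counts", "expected", "background_subtracted", "smoothed")

#' StrandedTrack: per-chromosome, per-strand single-nucleotide signal
#'
#' Container for strand-specific single-nucleotide signal across a genome.
#' Each strand holds one numeric vector per chromosome whose length equals the
#' chromosome length; position `p` (0-based) is stored at index `p + 1`.
#' Raw-count tracks are non-negative integers; background-subtracted tracks
#' may be negative.
#'
#' @slot plus named list of numeric vectors, one per chromosome (+ strand).
#' @slot minus named list of numeric vectors, one per chromosome (- strand).
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot sample sample identifier.
#' @slot state processing state, one of `"raw_counts"`, `"expected"`,
#'   `"background_subtracted"`, `"smoothed"`.
#'
#' @seealso [strandedTrack()], [narrowTo3Prime()], [subtractBackground()]
#' @export
setClass("StrandedTrack",
  representation(plus = "list", minus = "list",
                 seqlengths = "integer", sample = "character",
                 state = "character"))

setValidity("StrandedTrack", function(object) {
  sl <- object@seqlengths
  msg <- character()
  if (is.null(names(sl)) || anyDuplicated(names(sl)))
    msg <- c(msg, "seqlengths must be uniquely named")
  for (s in c("plus", "minus")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(names(sl)))) {
      msg <- c(msg, sprintf("%s strand chromosomes do not match seqlengths", s))
      next
    }
    len_ok <- vapply(names(sl), function(ch) length(v[[ch]]) == sl[[ch]],
                     logical(1))
    if (!all(len_ok))
      msg <- c(msg, sprintf("%s strand vector length != chromosome length: %s",
                            s, paste(names(sl)[!len_ok], collapse = ", ")))
  }
  if (length(object@state) != 1L || !object@state %in% .TRACK_STATES)
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.TRACK_STATES, collapse = ", ")))
  if (object@state == "raw_counts") {
    allv <- unlist(c(object@plus, object@minus), use.names = FALSE)
    if (length(allv) && (min(allv) < 0 || any(allv != floor(allv))))
      msg <- c(msg, "raw_counts state requires non-negative integer signal")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StrandedTrack
#'
#' @param plus,minus named lists of per-chromosome signal vectors. Missing
#'   chromosomes are filled with zeros.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param sample sample identifier.
#' @param state processing state (see [StrandedTrack-class]).
#' @return A [StrandedTrack-class] object.
#' @examples
#' sl <- c(chrI = 100L)
#' tr <- strandedTrack(plus = list(chrI = rep(0, 100)), seqlengths = sl)
#' @export
strandedTrack <- function(plus = list(), minus = list(), seqlengths,
                          sample = "sample", state = "raw_counts") {
  nm <- names(seqlengths)
  seqlengths <- as.integer(round(seqlengths))
  names(seqlengths) <- nm
  fill <- function(lst) {
    out <- lapply(names(seqlengths), function(ch) {
      if (!is.null(lst[[ch]])) as.numeric(lst[[ch]]) else numeric(seqlengths[[ch]])
    })
    names(out) <- names(seqlengths)
    out
  }
  new("StrandedTrack", plus = fill(plus), minus = fill(minus),
      seqlengths = seqlengths, sample = sample, state = state)
}

#' @describeIn StrandedTrack-class chromosome lengths of a track
#' @param x,object a `StrandedTrack`
#' @importFrom GenomeInfoDb seqlengths
#' @exportMethod seqlengths
setMethod("seqlengths", "StrandedTrack", function(x) x@seqlengths)

#' Extract the per-nucleotide signal vector of one chromosome/strand
#'
#' @param x a [StrandedTrack-class].
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of length `seqlengths(x)[chrom]`; index `i` holds
#'   the signal at 0-based position `i - 1`.
#' @export
setGeneric("trackSignal", function(x, chrom, strand) standardGeneric("trackSignal"))

#' @rdname trackSignal
#' @export
setMethod("trackSignal", "StrandedTrack", function(x, chrom, strand) {
  if (!chrom %in% names(x@seqlengths))
    stop("unknown chromosome: ", chrom)
  strand <- match.arg(strand, c("+", "-"))
  if (strand == "+") x@plus[[chrom]] else x@minus[[chrom]]
})

#' Processing state of a track
#'
#' @param x a [StrandedTrack-class].
#' @return character scalar state.
#' @export
setGeneric("trackState", function(x) standardGeneric("trackState"))

#' @rdname trackState
#' @export
setMethod("trackState", "StrandedTrack", function(x) x@state)

#' Total signal mass of a track (both strands)
#'
#' @param x a [StrandedTrack-class].
#' @return numeric scalar.
#' @export
setGeneric("trackTotal", function(x) standardGeneric("trackTotal"))

#' @rdname trackTotal
#' @export
setMethod("trackTotal", "StrandedTrack", function(x) {
  sum(vapply(x@plus, sum, numeric(1))) + sum(vapply(x@minus, sum, numeric(1)))
})

setMethod("show", "StrandedTrack", function(object) {
  cat("StrandedTrack '", object@sample, "' [", object@state, "]\n", sep = "")
  cat("  ", length(object@seqlengths), " chromosome(s), ",
      format(sum(as.numeric(object@seqlengths)), big.mark = ","),
      " nt; total signal ", format(trackTotal(object)), "\n", sep = "")
})

#' BinnedProfile: anchor-aligned binned metagene summary
#'
#' Result of a metagene computation: for each bin of the anchor-aligned grid,
#' the trimmed-mean summary value and the number of per-gene (or per-instance)
#' values that contributed before trimming. Bins are labelled by the offset of
#' their 5' edge from the anchor, in transcription-direction nucleotides.
#'
#' @slot offset integer vector of bin 5'-edge offsets relative to the anchor.
#' @slot value numeric per-bin summary (NA where no gene was eligible).
#' @slot n integer per-bin count of contributing values (before trimming).
#' @slot anchor anchor type (`"TSS"`, `"PAS"`, `"nucleosome_center"`).
#' @slot bin bin width in nt.
#' @slot trim trim fraction applied per tail.
#' @export
setClass("BinnedProfile",
  representation(offset = "integer", value = "numeric", n = "integer",
                 anchor = "character", bin = "integer", trim = "numeric"))

setValidity("BinnedProfile", function(object) {
  msg <- character()
  if (length(object@offset) != length(object@value) ||
      length(object@offset) != length(object@n))
    msg <- c(msg, "offset, value and n must have equal length")
  if (is.unsorted(object@offset, strictly = TRUE))
    msg <- c(msg, "bins must be ordered by offset")
  if (object@trim < 0 || object@trim >= 0.5)
    msg <- c(msg, "trim must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinnedProfile", function(object) {
  cat("BinnedProfile (", object@anchor, "-anchored, ", object@bin,
      "-nt bins, trim ", object@trim, ")\n", sep = "")
  cat("  ", length(object@offset), " bins spanning [",
      min(object@offset), ", ", max(object@offset) + object@bin, ") nt; ",
      sum(!is.na(object@value)), " non-missing\n", sep = "")
})

#' @export
#' @describeIn BinnedProfile-class convert to a data.frame with columns
#'   `offset` (bin 5' edge), `center` (bin midpoint), `value`, `n`
#' @param x a `BinnedProfile`
#' @param ... unused
as.data.frame.BinnedProfile <- function(x, ...) {
  data.frame(offset = x@offset, center = x@offset + x@bin / 2,
             value = x@value, n = x@n)
}

#' Per-bin values of a profile
#'
#' @param x a [BinnedProfile-class].
#' @return named numeric vector (names = bin 5'-edge offsets).
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname profileValues
#' @export
setMethod("profileValues", "BinnedProfile", function(x) {
  stats::setNames(x@value, x@offset)
})

#' Bin 5'-edge offsets of a profile
#'
#' @param x a [BinnedProfile-class].
#' @return integer vector.
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @rdname profileOffsets
#' @export
setMethod("profileOffsets", "BinnedProfile", function(x) x@offset)

#' BackgroundModel: calibration of non-tag-specific signal
#'
#' A single global scalar relating the no-tag control track to the
#' non-specific component of a tagged-IP track, fitted either from bin
#' ratios over a Pol3-transcribed control gene (`"scr1_bins"`, single IP) or
#' from total library sizes (`"total_reads"`, sequential IP).
#'
#' @slot ratio non-negative scalar: tagged/no-tag background ratio.
#' @slot method `"scr1_bins"` or `"total_reads"`.
#' @slot region list(chrom, start, end, strand) of the control interval
#'   (0-based half-open), or empty list for `"total_reads"`.
#' @slot bin bin width used (nt).
#' @slot trims integer(2): nt trimmed from region start and end.
#' @slot n_bins number of bins entering the ratio mean.
#' @export
setClass("BackgroundModel",
  representation(ratio = "numeric", method = "character", region = "list",
                 bin = "integer", trims = "integer", n_bins = "integer"))

setValidity("BackgroundModel", function(object) {
  msg <- character()
  if (length(object@ratio) != 1L || is.na(object@ratio) || object@ratio < 0)
    msg <- c(msg, "ratio must be a single non-negative number")
  if (!object@method %in% c("scr1_bins", "total_reads"))
    msg <- c(msg, "method must be 'scr1_bins' or 'total_reads'")
  if (object@method == "scr1_bins" && length(object@region) == 0)
    msg <- c(msg, "scr1_bins method requires a control region")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel (", object@method, "): ratio = ",
      format(object@ratio, digits = 6), "\n", sep = "")
  if (object@method == "scr1_bins")
    cat("  region ", object@region$chrom, ":", object@region$start, "-",
        object@region$end, " (", object@region$strand, "), ",
        object@n_bins, " bins of ", object@bin, " nt\n", sep = "")
})

#' Fitted background ratio
#'
#' @param x a [BackgroundModel-class].
#' @return numeric scalar.
#' @export
setGeneric("backgroundRatio", function(x) standardGeneric("backgroundRatio"))

#' @rdname backgroundRatio
#' @export
setMethod("backgroundRatio", "BackgroundModel", function(x) x@ratio)

#' DivergentPairSet: divergently expressed gene pairs over a gene universe
#'
#' @slot pairs data.frame with character columns `gene1` (minus-strand gene)
#'   and `gene2` (plus-strand gene) and integer column `separation`
#'   (TSS-to-TSS distance in nt).
#' @slot universe the gene ids the pairs were derived from.
#' @export
setClass("DivergentPairSet",
  representation(pairs = "data.frame", universe = "character"))

setValidity("DivergentPairSet", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("gene1", "gene2") %in% names(p)))
    msg <- c(msg, "pairs must have columns gene1 and gene2")
  else {
    if (any(p$gene1 == p$gene2))
      msg <- c(msg, "a gene cannot pair with itself")
    if (!all(c(p$gene1, p$gene2) %in% object@universe))
      msg <- c(msg, "pairs must be drawn from the universe")
  }
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe ids must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DivergentPairSet", function(object) {
  cat("DivergentPairSet: ", nrow(object@pairs), " pair(s) over ",
      length(object@universe), " genes\n", sep = "")
})

#' Pair table of a DivergentPairSet
#'
#' @param x a [DivergentPairSet-class].
#' @return data.frame with columns `gene1`, `gene2`, `separation`.
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pairTable
#' @export
setMethod("pairTable", "DivergentPairSet", function(x) x@pairs)

#' Gene universe of a DivergentPairSet
#'
#' @param x a [DivergentPairSet-class].
#' @return character vector of gene ids.
#' @export
setGeneric("pairUniverse", function(x) standardGeneric("pairUniverse"))

#' @rdname pairUniverse
#' @export
setMethod("pairUniverse", "DivergentPairSet", function(x) x@universe)

#' PermutationResult: permutation enrichment of pairs in a gene group
#'
#' @slot observed observed number of pairs with both members in the group.
#' @slot null_counts integer vector of pair counts in each random resample.
#' @slot p_enrich add-one permutation p for enrichment (null >= observed).
#' @slot p_deplete add-one permutation p for depletion (null <= observed).
#' @slot n_samples number of resamples.
#' @slot seed RNG seed used (NA if none supplied).
#' @export
setClass("PermutationResult",
  representation(observed = "integer", null_counts = "integer",
                 p_enrich = "numeric", p_deplete = "numeric",
                 n_samples = "integer", seed = "integer"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@null_counts) != object@n_samples)
    msg <- c(msg, "null_counts length must equal n_samples")
  pe <- (sum(object@null_counts >= object@observed) + 1) /
    (object@n_samples + 1)
  if (abs(pe - object@p_enrich) > 1e-12)
    msg <- c(msg, "p_enrich inconsistent with add-one convention")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed = ", object@observed,
      ", null mean = ", format(mean(object@null_counts), digits = 4),
      " (", object@n_samples, " resamples)\n",
      "  p(enrichment) = ", format(object@p_enrich, digits = 4),
      ", p(depletion) = ", format(object@p_deplete, digits = 4), "\n",
      sep = "")
})
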