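# Subtraction of non-tag-specific signal.
#
# Tagged-IP libraries contain a background of degraded mature transcripts
# that is also captured by an IP from an untagged strain. A single global
# scalar relates the two: for single IPs it is calibrated as the mean
# tagged/no-tag bin ratio over a Pol3-transcribed control gene (where no
# Pol2-elongation-factor signal is expected); for sequential IPs it is the
# ratio of total library sizes.

# Default control interval: the SCR1 gene window chrV:442007-442458 (1-based
# inclusive, SGD), stored 0-based half-open.
.SCR1_REGION <- list(chrom = "chrV", start = 442006L, end = 442458L,
                     strand = "+")

#' Default control region for background calibration (SCR1)
#'
#' The Pol3-transcribed SCR1 gene window, 0-based half-open, converted from
#' the 1-based SGD interval chrV:442007-442458.
#'
#' @return list with `chrom`, `start`, `end`, `strand`.
#' @export
scr1Region <- function() .SCR1_REGION

#' Fit the background ratio from control-gene bin ratios (single IP)
#'
#' The control region, minus its first `trim_start` and last `trim_end`
#' nucleotides, is divided into consecutive `bin`-nt bins (a final partial
#' bin is dropped). For every bin with a positive no-tag count the
#' tagged/no-tag count ratio is formed, and the model ratio is the arithmetic
#' mean of these bin ratios.
#'
#' @param tagged,notag [StrandedTrack-class] raw-count tracks sharing a
#'   genome.
#' @param region control interval as `list(chrom, start, end, strand)`,
#'   0-based half-open; default [scr1Region()]. `strand = NULL` sums both
#'   strands.
#' @param bin bin width in nt (default 10).
#' @param trim_start,trim_end nucleotides dropped from the region start/end
#'   (defaults 20 and 50).
#' @return a [BackgroundModel-class] with method `"scr1_bins"`.
#' @export
fitScr1Ratio <- function(tagged, notag, region = scr1Region(), bin = 10L,
                         trim_start = 20L, trim_end = 50L) {
  .checkSameGenome(tagged, notag)
  sl <- seqlengths(tagged)
  if (!region$chrom %in% names(sl))
    stop("control region chromosome not in track: ", region$chrom)
  if (region$start < 0 || region$end > sl[[region$chrom]])
    stop("control region lies outside the chromosome")
  extract <- function(track) {
    if (is.null(region$strand))
      trackSignal(track, region$chrom, "+") +
        trackSignal(track, region$chrom, "-")
    else
      trackSignal(track, region$chrom, region$strand)
  }
  i0 <- region$start + trim_start
  i1 <- region$end - trim_end            # half-open
  if (i1 - i0 < bin)
    stop("control region too short after trimming for a single bin")
  nb <- (i1 - i0) %/% bin                # final partial bin dropped
  sel <- (i0 + 1L):(i0 + nb * bin)       # 1-based vector indices
  f <- rep(seq_len(nb), each = bin)
  tag_bins <- as.numeric(tapply(extract(tagged)[sel], f, sum))
  bg_bins <- as.numeric(tapply(extract(notag)[sel], f, sum))
  ok <- bg_bins > 0
  if (!any(ok))
    stop("cannot calibrate background: all no-tag control bins are zero")
  if (sum(!ok) > length(ok) / 2)
    warning("background calibration: more than half of the control bins ",
            "have zero no-tag counts (", sum(!ok), "/", length(ok), ")")
  strand <- if (is.null(region$strand)) "*" else region$strand
  new("BackgroundModel", ratio = mean(tag_bins[ok] / bg_bins[ok]),
      method = "scr1_bins",
      region = list(chrom = region$chrom, start = region$start,
                    end = region$end, strand = strand),
      bin = as.integer(bin),
      trims = as.integer(c(trim_start, trim_end)),
      n_bins = as.integer(sum(ok)))
}

#' Fit the background ratio from total read counts (sequential IP)
#'
#' @param tagged_total,notag_total total reads (before alignment) of the
#'   tagged and no-tag libraries.
#' @return a [BackgroundModel-class] with method `"total_reads"`.
#' @examples
#' backgroundRatio(fitTotalReadRatio(2e6, 1e6))  # 2
#' @export
fitTotalReadRatio <- function(tagged_total, notag_total) {
  if (notag_total <= 0)
    stop("no-tag total read count must be positive")
  if (tagged_total < 0)
    stop("tagged total read count must be non-negative")
  new("BackgroundModel", ratio = tagged_total / notag_total,
      method = "total_reads", region = list(), bin = NA_integer_,
      trims = c(NA_integer_, NA_integer_), n_bins = NA_integer_)
}

#' Subtract scaled no-tag background from a tagged track
#'
#' Computes `tagged - ratio * notag` at every position on both strands.
#' Negative values are retained by default, so downstream trimmed-mean
#' profile statistics see the full signal distribution; `clamp = "zero"`
#' replaces negatives with zero (used only for heatmaps).
#'
#' @param tagged,notag [StrandedTrack-class] tracks sharing a genome.
#' @param model a fitted [BackgroundModel-class].
#' @param clamp `"none"` (default) or `"zero"`.
#' @return a [StrandedTrack-class] in state `"background_subtracted"`.
#' @export
subtractBackground <- function(tagged, notag, model,
                               clamp = c("none", "zero")) {
  clamp <- match.arg(clamp)
  .checkSameGenome(tagged, notag)
  stopifnot(is(model, "BackgroundModel"))
  r <- backgroundRatio(model)
  sub <- function(a, b) {
    out <- Map(function(x, y) {
      v <- x - r * y
      if (clamp == "zero") pmax(v, 0) else v
    }, a, b)
    out
  }
  strandedTrack(plus = sub(tagged@plus, notag@plus),
                minus = sub(tagged@minus, notag@minus),
                seqlengths = seqlengths(tagged),
                sample = tagged@sample, state = "background_subtracted")
}

.checkSameGenome <- function(a, b) {
  if (!identical(seqlengths(a), seqlengths(b)))
    stop("tracks do not share the same genome (seqlengths differ)")
  invisible(TRUE)
}

#' Serialize/deserialize a BackgroundModel as a JSON sidecar
#'
#' @param model a [BackgroundModel-class].
#' @param path JSON file path.
#' @return `writeBackgroundModel`: `path`, invisibly;
#'   `readBackgroundModel`: the model.
#' @export
writeBackgroundModel <- function(model, path) {
  x <- list(method = model@method, ratio = model@ratio,
            region = model@region, bin = model@bin,
            trims = model@trims, n_bins = model@n_bins)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeBackgroundModel
#' @export
readBackgroundModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_or_na <- function(v, n = 1L) {
    if (is.null(v) || !length(v)) rep(NA_integer_, n) else as.integer(v)
  }
  new("BackgroundModel", ratio = as.numeric(x$ratio), method = x$method,
      region = if (length(x$region)) x$region else list(),
      bin = int_or_na(x$bin), trims = int_or_na(x$trims, 2L),
      n_bins = int_or_na(x$n_bins))
}
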