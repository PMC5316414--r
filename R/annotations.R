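# Gene annotations: unique per-gene transcript records and divergent pairs.
#
# All in-memory coordinates are 0-based half-open on the forward genomic
# axis. Input/output text files use 1-based inclusive coordinates (SGD
# convention) and are converted at the I/O boundary.

.BIOTYPES <- c("mRNA", "stable_lncRNA", "unstable_lncRNA", "other")

#' Validate a gene annotation table
#'
#' A gene annotation table is a data.frame with one row per gene and columns
#' `gene_id`, `chrom`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based
#' half-open genomic span), `biotype`, and optionally `intron_bounds` (a list
#' column; per gene either `NULL` or a data.frame with genomic 0-based columns
#' `exon3` and `intron3`, the 3'-most transcribed nucleotide of the exon
#' preceding each intron and of the intron itself).
#'
#' @param genes candidate annotation data.frame.
#' @return `genes`, invisibly, after validation.
#' @export
validateAnnotations <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in annotation table: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- which(!(genes$start < genes$end) | genes$start < 0)
  if (length(bad))
    stop("malformed coordinates (need 0 <= start < end) for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  invisible(genes)
}

#' TSS and TES positions of annotated genes
#'
#' The TSS is the first transcribed nucleotide and the TES/PAS the last, both
#' as 0-based genomic positions; for minus-strand genes the TSS is therefore
#' the high-coordinate end of the span.
#'
#' @param genes validated annotation table.
#' @return integer vector of positions, named by `gene_id`.
#' @export
geneTss <- function(genes) {
  stats::setNames(ifelse(genes$strand == "+", genes$start, genes$end - 1L),
                  genes$gene_id)
}

#' @rdname geneTss
#' @export
geneTes <- function(genes) {
  stats::setNames(ifelse(genes$strand == "+", genes$end - 1L, genes$start),
                  genes$gene_id)
}

#' @rdname geneTss
#' @export
geneLength <- function(genes) {
  stats::setNames(genes$end - genes$start, genes$gene_id)
}

#' Select one annotation per gene from a transcript isoform table
#'
#' For each gene the most abundant isoform is kept; abundance ties are broken
#' by maximal length and remaining ties by lexicographic isoform id, so the
#' output is deterministic. Applying the selection to its own output returns
#' it unchanged.
#'
#' @param isoforms data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), `abundance` (non-negative expression
#'   measure, e.g. in rich medium), `biotype`, and optionally `isoform_id`.
#' @return gene annotation table (see [validateAnnotations()]), one row per
#'   `gene_id`, sorted by chromosome then TSS.
#' @examples
#' iso <- data.frame(gene_id = c("g1", "g1"), chrom = "chrI", strand = "+",
#'                   start = c(0, 0), end = c(400, 300),
#'                   abundance = c(5, 10), biotype = "mRNA")
#' selectIsoforms(iso)$end  # 300: the abundance-10 isoform wins
#' @export
selectIsoforms <- function(isoforms) {
  if (nrow(isoforms) == 0) {
    out <- isoforms[, intersect(names(isoforms),
                                c("gene_id", "chrom", "strand", "start",
                                  "end", "abundance", "biotype")), drop = FALSE]
    return(out)
  }
  req <- c("gene_id", "chrom", "strand", "start", "end", "abundance", "biotype")
  miss <- setdiff(req, names(isoforms))
  if (length(miss))
    stop("isoform table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(isoforms$gene_id)) || any(isoforms$gene_id == ""))
    stop("every isoform record needs a gene_id")
  if (any(is.na(isoforms$abundance)) || any(isoforms$abundance < 0))
    stop("abundance must be non-negative for all records")
  bad <- which(!(isoforms$start < isoforms$end) | isoforms$start < 0)
  if (length(bad)) {
    lab <- if (!is.null(isoforms$isoform_id)) isoforms$isoform_id[bad]
           else paste0(isoforms$gene_id[bad], " (row ", bad, ")")
    stop("malformed coordinates for isoform record(s): ",
         paste(lab, collapse = ", "))
  }
  iso_id <- if (!is.null(isoforms$isoform_id)) as.character(isoforms$isoform_id)
            else sprintf("iso%08d", seq_len(nrow(isoforms)))
  len <- isoforms$end - isoforms$start
  # order so the chosen isoform is the first row of each gene
  o <- order(isoforms$gene_id, -isoforms$abundance, -len, iso_id)
  first <- o[!duplicated(isoforms$gene_id[o])]
  out <- isoforms[first, c("gene_id", "chrom", "strand", "start", "end",
                           "abundance", "biotype")]
  tss <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out <- out[order(out$chrom, tss, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  validateAnnotations(out)
  out
}

#' Find divergently expressed gene pairs
#'
#' A divergent pair is a minus-strand gene A and a plus-strand gene B
#' transcribed in opposite directions away from each other, with
#' `0 < tss(B) - tss(A) <= max_separation` and no other gene from the input
#' list between the two TSSs. By default "between" is judged on TSS positions
#' only; `between = "span"` additionally blocks a pair when any third gene's
#' body overlaps the inter-TSS interval.
#'
#' @param genes validated annotation table (the pair universe).
#' @param max_separation maximal TSS-to-TSS distance in nt (default 1200).
#' @param between `"tss"` (default) or `"span"`: how an intervening gene is
#'   detected.
#' @return a [DivergentPairSet-class].
#' @export
findDivergentPairs <- function(genes, max_separation = 1200,
                               between = c("tss", "span")) {
  validateAnnotations(genes)
  between <- match.arg(between)
  stopifnot(max_separation > 0)
  tss <- geneTss(genes)
  res <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    t <- tss[g$gene_id]
    for (i in which(g$strand == "-")) {
      cand <- which(g$strand == "+" & t > t[i] & t - t[i] <= max_separation)
      for (j in cand) {
        blocked <- any(t > t[i] & t < t[j])
        if (!blocked && between == "span") {
          k <- setdiff(seq_len(nrow(g)), c(i, j))
          blocked <- any(g$start[k] < t[j] & g$end[k] > t[i] + 1L)
        }
        if (!blocked)
          res[[length(res) + 1L]] <- data.frame(
            gene1 = g$gene_id[i], gene2 = g$gene_id[j],
            separation = as.integer(t[j] - t[i]))
      }
    }
  }
  pairs <- if (length(res)) do.call(rbind, res)
           else data.frame(gene1 = character(), gene2 = character(),
                           separation = integer())
  pairs <- pairs[order(pairs$gene1, pairs$gene2), , drop = FALSE]
  rownames(pairs) <- NULL
  new("DivergentPairSet", pairs = pairs, universe = genes$gene_id)
}

# ---- I/O ----

#' Read a transcript isoform table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `strand`, `start`,
#' `end`, `abundance`, `biotype` (optionally `isoform_id`); `start`/`end` are
#' 1-based inclusive and are converted to the internal 0-based half-open
#' convention.
#'
#' @param path TSV file path.
#' @return isoform data.frame ready for [selectIsoforms()].
#' @export
readIsoformTable <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  x$start <- as.integer(x$start) - 1L  # 1-based inclusive -> 0-based half-open
  x$end <- as.integer(x$end)
  x
}

#' Write/read gene annotations as BED6 plus a sidecar TSV
#'
#' The BED6 file (`<prefix>.bed`) carries the 0-based half-open span, the
#' gene id as name, score 0 and the strand. The sidecar (`<prefix>.meta.tsv`)
#' carries `gene_id`, `biotype` and serialized intron bounds
#' (`exon3:intron3` pairs joined by `;`, 0-based genomic positions).
#'
#' @param genes annotation table.
#' @param prefix output path prefix.
#' @return `writeAnnotations`: the two file paths, invisibly.
#'   `readAnnotations`: the annotation table.
#' @export
writeAnnotations <- function(genes, prefix) {
  validateAnnotations(genes)
  bed <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                    name = genes$gene_id, score = 0L, strand = genes$strand)
  bed_path <- paste0(prefix, ".bed")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ib <- rep("", nrow(genes))
  if (!is.null(genes$intron_bounds))
    ib <- vapply(genes$intron_bounds, function(b) {
      if (is.null(b) || nrow(b) == 0) "" else
        paste(sprintf("%d:%d", b$exon3, b$intron3), collapse = ";")
    }, character(1))
  meta <- data.frame(gene_id = genes$gene_id, biotype = genes$biotype,
                     intron_bounds = ib)
  meta_path <- paste0(prefix, ".meta.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, meta = meta_path))
}

#' @rdname writeAnnotations
#' @param prefix path prefix used when writing.
#' @export
readAnnotations <- function(prefix) {
  bed <- utils::read.table(paste0(prefix, ".bed"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  meta <- utils::read.table(paste0(prefix, ".meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            na.strings = NULL,
                            colClasses = c("character", "character",
                                           "character"))
  genes <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                      strand = bed$strand, start = bed$start, end = bed$end,
                      biotype = meta$biotype[match(bed$name, meta$gene_id)])
  ib_str <- meta$intron_bounds[match(bed$name, meta$gene_id)]
  if (any(!is.na(ib_str) & ib_str != "")) {
    genes$intron_bounds <- lapply(ib_str, function(s) {
      if (is.na(s) || s == "") return(NULL)
      parts <- strsplit(strsplit(s, ";")[[1]], ":")
      data.frame(exon3 = as.integer(vapply(parts, `[`, "", 1)),
                 intron3 = as.integer(vapply(parts, `[`, "", 2)))
    })
  }
  validateAnnotations(genes)
  genes
}

#' Write a divergent pair set as a two-column TSV
#'
#' @param pairs a [DivergentPairSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePairs <- function(pairs, path) {
  utils::write.table(pairTable(pairs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
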