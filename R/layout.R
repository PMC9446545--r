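#' Define a genome layout
#'
#' A genome layout is the coordinate space every other object is validated
#' against: an ordered set of chromosome names with their lengths. It is
#' represented as a \code{GenomeInfoDb::Seqinfo} so that ranges built on it
#' inherit the chromosome bounds.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp, all positive.
#' @return A \code{Seqinfo} object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1.5e6))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms))
    stop("chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(chroms))
    stop("'chroms' and 'lengths' must have the same length")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Read and write chrom-sizes files
#'
#' Two-column TSV of chromosome name and length, the conventional sidecar of
#' BED-family formats.
#'
#' @param path file path.
#' @return \code{read_chrom_sizes} returns a \code{Seqinfo};
#'   \code{write_chrom_sizes} returns \code{path} invisibly.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "numeric"))
  genome_layout(tab$chrom, tab$length)
}

#' @rdname read_chrom_sizes
#' @param layout a \code{Seqinfo} genome layout.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(is(layout, "Seqinfo"))
  writeLines(paste(seqnames(layout), seqlengths(layout), sep = "\t"), path)
  invisible(path)
}

# Validate that a GRanges lies within its layout; used by all readers.
validate_on_layout <- function(gr, layout, what = "interval") {
  sn <- as.character(seqnames(gr))
  unknown <- !(sn %in% seqnames(layout))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("unknown chromosome '", sn[i], "' for ", what, " ", i)
  }
  lens <- seqlengths(layout)[sn]
  bad <- start(gr) < 1L | end(gr) > lens
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(what, " ", i, " (", sn[i], ":", start(gr)[i] - 1L, "-", end(gr)[i],
         ") extends outside chromosome bounds")
  }
  seqlevels(gr) <- seqnames(layout)
  seqinfo(gr) <- layout
  gr
}
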