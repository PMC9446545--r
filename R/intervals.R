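#' Construct a peak set
#'
#' A peak set is a sorted \code{GRanges} of scored intervals from one assay
#' and genotype. Optional metadata columns follow the narrowPeak-flavoured
#' convention used throughout the package: \code{fold_enrichment} (observed
#' over expected window count), \code{score} (-log10 p or q) and
#' \code{summit} (bp offset of the maximum from the peak start).
#'
#' @param gr a \code{GRanges} (or anything coercible to one).
#' @param assay assay label, e.g. \code{"ZCWPW1"}, \code{"H3K9ac"},
#'   \code{"ATAC"}, \code{"DMC1"}.
#' @param genotype genotype label, e.g. \code{"WT"}, \code{"Zcwpw1KO"},
#'   \code{"Prdm9KO"}, \code{"Spo11KO"}.
#' @param layout optional \code{Seqinfo}; when given, intervals are validated
#'   against it.
#' @return A sorted \code{GRanges} with \code{metadata()} fields \code{assay}
#'   and \code{genotype}.
#' @export
peak_set <- function(gr, assay = NA_character_, genotype = NA_character_,
                     layout = NULL) {
  gr <- as(gr, "GRanges")
  if (!is.null(layout))
    gr <- validate_on_layout(gr, layout, what = "peak")
  gr <- sort(sortSeqlevels(gr), ignore.strand = TRUE)
  metadata(gr)$assay <- assay
  metadata(gr)$genotype <- genotype
  gr
}

#' Read a BED file into a peak set
#'
#' Accepts BED3 through BED6 plus two optional numeric extensions used by the
#' package's writers: column 7 is fold enrichment, column 8 is the summit
#' offset. Coordinates on disk are 0-based half-open and are converted to the
#' in-memory 1-based closed \code{GRanges} convention. Lines starting with
#' \code{track}, \code{browser} or \code{#} are skipped.
#'
#' @param path path to a BED file.
#' @param layout a \code{Seqinfo}; every record must fall inside it.
#' @inheritParams peak_set
#' @return A sorted \code{GRanges} peak set.
#' @seealso \code{\link{write_bed}}
#' @export
read_bed <- function(path, layout, assay = NA_character_,
                     genotype = NA_character_) {
  stopifnot(is(layout, "Seqinfo"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(peak_set(GRanges(seqinfo = layout), assay, genotype))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 columns")
  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  start0 <- suppressWarnings(as.numeric(col(2)))
  end0 <- suppressWarnings(as.numeric(col(3)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0
  if (any(bad))
    stop("malformed BED line ", lineno[which(bad)[1L]],
         ": invalid start/end")
  chrom <- col(1)
  unknown <- !(chrom %in% seqnames(layout))
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop("BED line ", lineno[i], ": unknown chromosome '", chrom[i], "'")
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  if (max(nf) >= 4L) {
    nm <- col(4)
    if (!all(is.na(nm))) mcols(gr)$name <- nm
  }
  if (max(nf) >= 5L)
    mcols(gr)$score <- suppressWarnings(as.numeric(col(5)))
  if (max(nf) >= 6L) {
    str <- col(6)
    str[is.na(str) | !(str %in% c("+", "-"))] <- "*"
    strand(gr) <- str
  }
  if (max(nf) >= 7L)
    mcols(gr)$fold_enrichment <- suppressWarnings(as.numeric(col(7)))
  if (max(nf) >= 8L)
    mcols(gr)$summit <- suppressWarnings(as.numeric(col(8)))
  peak_set(gr, assay, genotype, layout = layout)
}

#' Write a peak set to BED
#'
#' Emits BED3 when no metadata columns are present, otherwise BED6 plus the
#' \code{fold_enrichment} and \code{summit} columns when available.
#' Coordinates are converted back to 0-based half-open.
#'
#' @param peaks a \code{GRanges} peak set.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(is(peaks, "GRanges"))
  chrom <- as.character(seqnames(peaks))
  s0 <- format_coord(start(peaks) - 1L)
  e0 <- format_coord(end(peaks))
  mc <- mcols(peaks)
  has_extra <- ncol(mc) > 0L || any(as.character(strand(peaks)) != "*")
  if (!has_extra) {
    out <- paste(chrom, s0, e0, sep = "\t")
  } else {
    nm <- if ("name" %in% colnames(mc)) as.character(mc$name)
          else paste0("peak_", seq_along(peaks))
    sc <- if ("score" %in% colnames(mc)) format_num(mc$score) else "0"
    str <- as.character(strand(peaks))
    str[str == "*"] <- "."
    out <- paste(chrom, s0, e0, nm, sc, str, sep = "\t")
    if ("fold_enrichment" %in% colnames(mc))
      out <- paste(out, format_num(mc$fold_enrichment), sep = "\t")
    if ("summit" %in% colnames(mc))
      out <- paste(out, format_num(mc$summit), sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

format_num <- function(x) {
  out <- sprintf("%.10g", as.numeric(x))
  out[is.na(x)] <- "."
  out
}

#' Pairwise overlap width of two intervals
#'
#' Returns the number of shared base pairs between parallel vectors of
#' intervals; 0 for intervals on different chromosomes or merely abutting
#' ones (half-open BED arithmetic: \code{[100,200)} and \code{[200,300)} do
#' not overlap). Strand is ignored.
#'
#' @param a,b \code{GRanges} of equal length (or length 1, recycled).
#' @return Integer vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"))
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  w <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  w[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  pmax(w, 0L)
}

#' Overlap expressed as a fraction of the second interval
#'
#' \code{overlap_bp(a, b) / width(b)}: the share of \code{b} covered by
#' \code{a}. This is the quantity behind the "overlaps at least 20\% of an
#' ATAC peak" openness rule, where \code{b} is the ATAC peak.
#'
#' @inheritParams overlap_bp
#' @return Numeric vector of fractions in \code{[0, 1]}.
#' @export
overlap_fraction_of_b <- function(a, b) {
  stopifnot(is(b, "GRanges"))
  ov <- overlap_bp(a, b)
  ov / rep_len(as.numeric(width(b)), length(ov))
}

#' Subset peaks of A having a qualifying partner in B
#'
#' Returns the peaks of \code{A} for which at least one single peak of
#' \code{B} overlaps by \code{min_bp} or more base pairs \emph{and} covers at
#' least \code{min_frac_of_b} of that B peak's length. Thresholds are
#' evaluated per partner, never summed across partners, and each A peak is
#' returned at most once, in sorted order.
#'
#' With \code{min_bp = 1, min_frac_of_b = 0} this is the "overlap by at least
#' 1 bp" marking rule; with \code{min_frac_of_b = 0.2} it is the openness
#' rule.
#'
#' @param A,B \code{GRanges} peak sets.
#' @param min_bp minimum overlap in bp (inclusive).
#' @param min_frac_of_b minimum fraction of the B partner's length covered
#'   (inclusive).
#' @return The qualifying subset of \code{A}.
#' @export
intersect_sets <- function(A, B, min_bp = 1L, min_frac_of_b = 0) {
  stopifnot(is(A, "GRanges"), is(B, "GRanges"))
  if (length(A) == 0L || length(B) == 0L) return(A[integer(0)])
  hits <- findOverlaps(A, B, minoverlap = max(1L, as.integer(min_bp)),
                       ignore.strand = TRUE)
  if (min_frac_of_b > 0 && length(hits)) {
    ov <- overlap_bp(A[queryHits(hits)], B[subjectHits(hits)])
    frac <- ov / width(B)[subjectHits(hits)]
    hits <- hits[frac >= min_frac_of_b]
  }
  A[sort(unique(queryHits(hits)))]
}

#' Read and write bedGraph signal tracks
#'
#' A bedGraph holds stepped per-base values in 0-based half-open intervals.
#' \code{read_bedgraph} returns a per-chromosome \code{RleList} defined on
#' every base of the layout, with gaps read as 0 (the convention for
#' fold-change-over-background tracks, which tile the genome).
#' \code{write_bedgraph} emits the non-zero runs.
#'
#' @param path file path.
#' @param layout a \code{Seqinfo}.
#' @return \code{read_bedgraph}: a named \code{RleList}, one run-length
#'   vector per chromosome, covering it entirely.
#' @export
read_bedgraph <- function(path, layout) {
  stopifnot(is(layout, "Seqinfo"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  track <- empty_track(layout)
  if (length(lines) == 0L) return(track)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stop("malformed bedGraph line ",
         lineno[which(lengths(fields) < 4L)[1L]], ": fewer than 4 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- is.na(s0) | is.na(e0) | is.na(val) | s0 < 0 | e0 <= s0
  if (any(bad))
    stop("malformed bedGraph line ", lineno[which(bad)[1L]])
  unknown <- !(chrom %in% seqnames(layout))
  if (any(unknown))
    stop("bedGraph line ", lineno[which(unknown)[1L]],
         ": unknown chromosome '", chrom[which(unknown)[1L]], "'")
  lens <- seqlengths(layout)[chrom]
  if (any(e0 > lens))
    stop("bedGraph line ", lineno[which(e0 > lens)[1L]],
         ": interval extends outside chromosome")
  gr <- GRanges(chrom, IRanges(s0 + 1, e0), value = val, seqinfo = layout)
  cov <- coverage(gr, weight = "value")
  cov[seqnames(layout)]
}

#' @rdname read_bedgraph
#' @param track a per-chromosome \code{RleList} as returned by
#'   \code{read_bedgraph} or \code{\link{normalize_fold_change}}.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- track[[chrom]]
    ends <- cumsum(runLength(r))
    starts0 <- ends - runLength(r)
    vals <- runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(paste(chrom, format_coord(starts0[keep]),
                     format_coord(ends[keep]), format_num(vals[keep]),
                     sep = "\t"), con)
  }
  invisible(path)
}

# An all-zero track covering the layout.
empty_track <- function(layout) {
  as(setNames(lapply(seqlengths(layout), function(L) Rle(0, L)),
              seqnames(layout)), "RleList")
}
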