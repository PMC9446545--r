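#' Fold-change normalization of a coverage track
#'
#' Converts raw coverage into a normalized signal track defined as treatment
#' over the background expectation, the representation used for all heatmaps
#' and loss/retention ratios. The denominator is floored at
#' \code{pseudocount} so that empty control regions cannot blow the ratio
#' up; where the control exceeds the pseudocount the value is exactly
#' \code{treatment / control}.
#'
#' @param treatment per-chromosome \code{RleList} of non-negative coverage.
#' @param control either a single per-bp background expectation (lambda), or
#'   an \code{RleList} control track parallel to \code{treatment}.
#' @param pseudocount positive floor applied to the denominator.
#' @return An \code{RleList} signal track of the same shape.
#' @export
normalize_fold_change <- function(treatment, control, pseudocount = 0.5) {
  if (pseudocount <= 0)
    stop("pseudocount must be positive")
  if (is.numeric(control) && length(control) == 1L) {
    denom <- max(control, pseudocount)
    return(treatment / denom)
  }
  stopifnot(identical(names(treatment), names(control)))
  as(setNames(lapply(names(treatment), function(chrom) {
    d <- control[[chrom]]
    d[d < pseudocount] <- pseudocount
    treatment[[chrom]] / d
  }), names(treatment)), "RleList")
}

#' Mean track value over intervals
#'
#' Per-interval mean of a stepped per-bp track, the statistic the loss
#' classifier compares between genotypes.
#'
#' @param track per-chromosome \code{RleList}.
#' @param gr a \code{GRanges}.
#' @return Numeric vector, one mean per range of \code{gr}.
#' @export
track_means <- function(track, gr) {
  out <- numeric(length(gr))
  sn <- as.character(seqnames(gr))
  for (chrom in unique(sn)) {
    idx <- which(sn == chrom)
    v <- Views(track[[chrom]], start = start(gr)[idx], end = end(gr)[idx])
    out[idx] <- viewMeans(v)
  }
  out
}

# Genome-wide mean of an RleList track.
track_mean <- function(track) {
  tot <- sum(vapply(track, function(r) sum(as.numeric(runValue(r)) *
                                           runLength(r)), numeric(1)))
  len <- sum(vapply(track, length, numeric(1)))
  tot / len
}
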