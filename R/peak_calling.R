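#' Configuration for the windowed Poisson peak caller
#'
#' The caller slides a fixed window along each chromosome, tests the window
#' count against a Poisson background, corrects for multiple testing where a
#' q-value threshold is configured, merges significant windows, and then
#' applies the fold-enrichment retention filter. The background expectation
#' per window (lambda) is either genome-wide or the maximum of the
#' genome-wide value and a local estimate from the window's flanks.
#'
#' Exactly one of \code{p_threshold} / \code{q_threshold} must be set: a raw
#' Poisson p-value cutoff, or a Benjamini-Hochberg q-value cutoff applied
#' over all scanned windows genome-wide.
#'
#' @param window window width in bp.
#' @param step distance between window starts in bp; \code{window >= step}.
#' @param genome_lambda expected count per window under the background; when
#'   \code{NULL} it is estimated as genome-wide mean coverage times
#'   \code{window}.
#' @param local_lambda_flank flank size in bp for local background
#'   estimation (\code{NULL} for genome-wide lambda only). The local lambda
#'   is the mean per-bp count over \code{flank} bp on each side of the
#'   window (window excluded), times \code{window}, floored at the
#'   genome-wide lambda.
#' @param p_threshold,q_threshold significance levels in (0, 1).
#' @param min_fold_enrichment peaks whose fold enrichment (maximum window
#'   count over lambda) is not strictly greater than this are discarded.
#' @param merge_gap significant windows closer than or equal to this many bp
#'   are merged into one peak.
#' @return A list of class \code{caller_config}.
#' @seealso \code{\link{caller_preset}} for the per-assay presets.
#' @export
caller_config <- function(window = 200L, step = 50L, genome_lambda = NULL,
                          local_lambda_flank = NULL, p_threshold = NULL,
                          q_threshold = NULL, min_fold_enrichment = 1,
                          merge_gap = 100L) {
  window <- as.integer(window); step <- as.integer(step)
  if (!(window >= step && step > 0L))
    stop("need window >= step > 0")
  if (is.null(p_threshold) == is.null(q_threshold))
    stop("set exactly one of p_threshold or q_threshold")
  thr <- c(p_threshold, q_threshold)
  if (thr <= 0 || thr >= 1)
    stop("significance threshold must lie in (0, 1)")
  if (min_fold_enrichment <= 0)
    stop("min_fold_enrichment must be positive")
  structure(list(window = window, step = step,
                 genome_lambda = genome_lambda,
                 local_lambda_flank = local_lambda_flank,
                 p_threshold = p_threshold, q_threshold = q_threshold,
                 min_fold_enrichment = min_fold_enrichment,
                 merge_gap = as.integer(merge_gap)),
            class = "caller_config")
}

#' Per-assay caller presets
#'
#' The four configurations used in the study's analyses:
#' \describe{
#'   \item{zcwpw1_chip}{raw p < 0.001, genome-wide lambda, fold enrichment
#'     must exceed 3.}
#'   \item{h3k9ac_chip}{q < 0.05 (BH), genome-wide lambda, no additional
#'     fold-enrichment filter beyond > 1.}
#'   \item{cutandtag}{q < 0.01, genome-wide lambda, fold enrichment > 10.}
#'   \item{atac}{q < 0.01, local lambda from a 10-kb flank on each side,
#'     fold enrichment > 4.}
#' }
#'
#' @param name one of \code{"zcwpw1_chip"}, \code{"h3k9ac_chip"},
#'   \code{"cutandtag"}, \code{"atac"}.
#' @param ... overrides passed to \code{\link{caller_config}}.
#' @return A \code{caller_config}.
#' @export
caller_preset <- function(name = c("zcwpw1_chip", "h3k9ac_chip",
                                   "cutandtag", "atac"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    zcwpw1_chip = list(p_threshold = 0.001, min_fold_enrichment = 3),
    h3k9ac_chip = list(q_threshold = 0.05, min_fold_enrichment = 1),
    cutandtag   = list(q_threshold = 0.01, min_fold_enrichment = 10),
    atac        = list(q_threshold = 0.01, min_fold_enrichment = 4,
                       local_lambda_flank = 10000L))
  do.call(caller_config, modifyList(args, list(...)))
}

#' Scan windows and compute Poisson enrichment p-values
#'
#' Tiling scan of a coverage track: per window the summed count, the
#' background expectation lambda, and the upper-tail Poisson probability
#' P(X >= count | lambda). A window with count 0 has p = 1 exactly.
#'
#' @param track per-chromosome \code{RleList} of coverage.
#' @param layout genome \code{Seqinfo}.
#' @param cfg a \code{\link{caller_config}}.
#' @return A \code{GRanges} of windows with metadata columns \code{count},
#'   \code{lambda} and \code{pvalue}.
#' @export
window_scan <- function(track, layout, cfg) {
  stopifnot(inherits(cfg, "caller_config"))
  if (cfg$window > min(seqlengths(layout)))
    stop("window (", cfg$window, " bp) larger than the smallest chromosome")
  glambda <- cfg$genome_lambda
  if (is.null(glambda)) glambda <- track_mean(track) * cfg$window
  res <- lapply(seqnames(layout), function(chrom) {
    L <- seqlengths(layout)[[chrom]]
    x <- as.numeric(track[[chrom]])
    cs <- c(0, cumsum(x))
    starts <- seq.int(1L, L - cfg$window + 1L, by = cfg$step)
    ends <- starts + cfg$window - 1L
    count <- cs[ends + 1L] - cs[starts]
    lambda <- rep(glambda, length(starts))
    if (!is.null(cfg$local_lambda_flank)) {
      fl <- cfg$local_lambda_flank
      a <- pmax(starts - fl, 1L)
      b <- pmin(ends + fl, L)
      flank_sum <- (cs[b + 1L] - cs[a]) - count
      flank_len <- (b - a + 1L) - cfg$window
      local <- ifelse(flank_len > 0, flank_sum / flank_len, 0) * cfg$window
      lambda <- pmax(lambda, local)
    }
    GRanges(chrom, IRanges(starts, ends), count = count, lambda = lambda,
            seqinfo = layout)
  })
  win <- do.call(c, unname(res))
  # P(X >= count): for fractional counts test exceedance of ceiling(count).
  win$pvalue <- ppois(ceiling(win$count) - 1, win$lambda, lower.tail = FALSE)
  win
}

#' Call peaks from a coverage track
#'
#' Runs \code{\link{window_scan}}, keeps windows below the configured p- or
#' BH-q threshold, merges significant windows separated by at most
#' \code{merge_gap} bp, annotates each merged peak with its fold enrichment
#' (maximum constituent window count over that window's lambda), the peak
#' score (-log10 of the best p or q) and the summit (offset of the maximum
#' window's midpoint from the peak start), and finally discards peaks whose
#' fold enrichment does not strictly exceed \code{min_fold_enrichment}.
#'
#' @inheritParams window_scan
#' @param assay,genotype labels attached to the returned peak set.
#' @return A sorted \code{GRanges} peak set with \code{fold_enrichment},
#'   \code{score} and \code{summit} metadata columns.
#' @export
call_peaks <- function(track, layout, cfg, assay = NA_character_,
                       genotype = NA_character_) {
  win <- window_scan(track, layout, cfg)
  if (is.null(cfg$q_threshold)) {
    stat <- win$pvalue
    sig <- stat < cfg$p_threshold
  } else {
    stat <- p.adjust(win$pvalue, method = "BH")
    sig <- stat < cfg$q_threshold
  }
  if (!any(sig))
    return(peak_set(GRanges(seqinfo = layout), assay, genotype))
  sw <- win[sig]
  sw$stat <- stat[sig]
  peaks <- reduce(sw, min.gapwidth = cfg$merge_gap + 1L,
                  ignore.strand = TRUE)
  hits <- findOverlaps(peaks, sw, ignore.strand = TRUE)
  fe_w <- sw$count / sw$lambda
  idx <- split(subjectHits(hits), queryHits(hits))
  fe <- numeric(length(peaks)); score <- numeric(length(peaks))
  summit <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    j <- idx[[as.character(i)]]
    best <- j[which.max(sw$count[j])]
    fe[i] <- fe_w[best]
    score[i] <- -log10(max(min(sw$stat[j]), .Machine$double.xmin))
    summit[i] <- (start(sw)[best] + end(sw)[best]) %/% 2L - start(peaks)[i]
  }
  peaks$fold_enrichment <- fe
  peaks$score <- score
  peaks$summit <- summit
  peaks <- peaks[fe > cfg$min_fold_enrichment]
  peak_set(peaks, assay, genotype)
}
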