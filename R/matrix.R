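#' Binned signal matrix around peak centers
#'
#' For every site, averages the signal track in consecutive bins across the
#' window \code{center - flank} to \code{center + flank}, the computation
#' behind reference-point heatmaps (default 40-bp bins over +/- 2 kb, i.e.
#' 100 bins). The center is the midpoint \code{floor((start0 + end0) / 2)} of
#' the site in 0-based coordinates. Bins truncated by a chromosome edge
#' average only their covered bases; bins entirely outside are 0.
#'
#' @param track per-chromosome \code{RleList} signal track.
#' @param sites a \code{GRanges} of sites (e.g. a ZCWPW1 peak set).
#' @param flank half-window in bp.
#' @param bin bin width in bp; must divide \code{2 * flank}.
#' @return An object of class \code{binned_matrix}: a list with elements
#'   \code{sites}, \code{flank}, \code{bin} and the numeric \code{values}
#'   matrix (sites x bins), row names \code{chrom:start0-end0}.
#' @export
compute_matrix <- function(track, sites, flank = 2000L, bin = 40L) {
  stopifnot(is(sites, "GRanges"))
  if (length(sites) == 0L) stop("'sites' is empty")
  flank <- as.integer(flank); bin <- as.integer(bin)
  if ((2L * flank) %% bin != 0L)
    stop("bin (", bin, ") must divide 2*flank (", 2L * flank, ")")
  nbins <- (2L * flank) %/% bin
  center0 <- (start(sites) - 1L + end(sites)) %/% 2L
  vals <- matrix(0, nrow = length(sites), ncol = nbins)
  sn <- as.character(seqnames(sites))
  for (chrom in unique(sn)) {
    idx <- which(sn == chrom)
    r <- track[[chrom]]
    L <- length(r)
    # 1-based closed coordinates of every (site, bin) cell
    bs <- rep(center0[idx] - flank, each = nbins) +
      rep.int(seq_len(nbins) - 1L, length(idx)) * bin + 1L
    be <- bs + bin - 1L
    cs <- pmax(bs, 1L); ce <- pmin(be, L)
    ok <- cs <= ce
    m <- numeric(length(bs))
    if (any(ok)) {
      v <- Views(r, start = cs[ok], end = ce[ok])
      m[ok] <- viewMeans(v)
    }
    vals[idx, ] <- matrix(m, ncol = nbins, byrow = TRUE)
  }
  rownames(vals) <- site_ids(sites)
  structure(list(sites = sites, flank = flank, bin = bin, values = vals),
            class = "binned_matrix")
}

# Stable site identifier in BED coordinates.
site_ids <- function(gr) {
  if (length(gr) == 0L) return(character(0))
  paste0(as.character(seqnames(gr)), ":", start(gr) - 1L, "-", end(gr))
}

#' Order sites by signal strength for heatmap display
#'
#' Computes a per-site statistic from one or more row-aligned binned
#' matrices and returns the permutation that sorts the sites from largest to
#' smallest, the ordering used in the study's heatmaps: either the average
#' signal across all samples (per-site mean of each matrix's row mean), or
#' the chosen statistic of a single named sample's rows. Ties are broken by
#' genomic position (chromosome then start, ascending).
#'
#' @param matrices a \code{binned_matrix} or list of them over identical
#'   sites; names identify samples for \code{across = "named_sample"}.
#' @param statistic \code{"mean"} or \code{"median"}, applied within each
#'   row.
#' @param across \code{"all_samples"} (average the per-sample row statistics)
#'   or \code{"named_sample"} (use \code{sample}'s rows only).
#' @param sample sample name, required for \code{across = "named_sample"}.
#' @return An integer permutation of the site indices.
#' @export
order_sites <- function(matrices, statistic = c("mean", "median"),
                        across = c("all_samples", "named_sample"),
                        sample = NULL) {
  statistic <- match.arg(statistic)
  across <- match.arg(across)
  if (inherits(matrices, "binned_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  ids <- lapply(matrices, function(m) site_ids(m$sites))
  if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
    stop("matrices are not row-aligned: site lists differ")
  rowstat <- function(m) {
    if (statistic == "mean") rowMeans(m$values)
    else apply(m$values, 1L, stats::median)
  }
  if (across == "all_samples") {
    stat <- rowMeans(do.call(cbind, lapply(matrices, rowstat)))
  } else {
    if (is.null(sample) || !(sample %in% names(matrices)))
      stop("'sample' must name one of the matrices")
    stat <- rowstat(matrices[[sample]])
  }
  sites <- matrices[[1L]]$sites
  order(-stat, as.character(seqnames(sites)), start(sites))
}

#' Meta-profile of a binned matrix
#'
#' The per-bin mean across sites: the curve shown by profile plots.
#'
#' @param mat a \code{binned_matrix}.
#' @return Numeric vector of length \code{ncol(mat$values)}.
#' @export
signal_profile <- function(mat) {
  stopifnot(inherits(mat, "binned_matrix"))
  colMeans(mat$values)
}

#' Export a binned matrix as TSV
#'
#' One row per site (id column then one column per bin), suitable for
#' downstream plotting.
#'
#' @param mat a \code{binned_matrix}.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(site = rownames(mat$values), mat$values,
                   check.names = FALSE)
  colnames(df) <- c("site", paste0("bin", seq_len(ncol(mat$values))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
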