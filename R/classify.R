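#' Mark reader binding sites carrying H3K9ac
#'
#' A ZCWPW1 binding site is "marked" when it overlaps a wild-type H3K9ac
#' peak by at least 1 bp.
#'
#' @param zcwpw1 \code{GRanges} of ZCWPW1 binding sites (WT).
#' @param h3k9ac_wt \code{GRanges} of WT H3K9ac peaks.
#' @return The marked subset of \code{zcwpw1}.
#' @export
mark_h3k9ac <- function(zcwpw1, h3k9ac_wt) {
  intersect_sets(zcwpw1, h3k9ac_wt, min_bp = 1L, min_frac_of_b = 0)
}

#' Find open reader binding sites
#'
#' A ZCWPW1 binding site is "open" when it covers at least a fraction
#' \code{min_frac} (default 20\%) of some single wild-type ATAC peak. The
#' fraction is measured on the ATAC peak's length by default; set
#' \code{frac_of = "site"} to measure it on the ZCWPW1 peak instead.
#'
#' @param zcwpw1 \code{GRanges} of ZCWPW1 binding sites (WT).
#' @param atac_wt \code{GRanges} of WT ATAC peaks.
#' @param min_frac inclusive minimum overlap fraction.
#' @param frac_of which interval's length the fraction refers to.
#' @return The open subset of \code{zcwpw1}.
#' @export
find_open_sites <- function(zcwpw1, atac_wt, min_frac = 0.2,
                            frac_of = c("atac_peak", "site")) {
  frac_of <- match.arg(frac_of)
  if (frac_of == "atac_peak")
    return(intersect_sets(zcwpw1, atac_wt, min_bp = 1L,
                          min_frac_of_b = min_frac))
  if (length(zcwpw1) == 0L || length(atac_wt) == 0L)
    return(zcwpw1[integer(0)])
  hits <- findOverlaps(zcwpw1, atac_wt, ignore.strand = TRUE)
  ov <- overlap_bp(zcwpw1[queryHits(hits)], atac_wt[subjectHits(hits)])
  keep <- ov / width(zcwpw1)[queryHits(hits)] >= min_frac
  zcwpw1[sort(unique(queryHits(hits)[keep]))]
}

#' Partition open sites into accessibility lost (A1) vs retained (A2)
#'
#' An open site loses accessibility (group A1) when its mean wild-type ATAC
#' signal is at least \code{ratio}-fold (inclusive) greater than in the
#' knockout; otherwise it retains it (group A2). Signals are normalized
#' fold-change tracks and the knockout mean receives a small pseudocount in
#' the denominator.
#'
#' @param open_sites \code{GRanges} of open ZCWPW1 sites.
#' @param atac_wt_signal,atac_ko_signal \code{RleList} fold-change tracks.
#' @param ratio inclusive loss threshold on WT/KO mean signal.
#' @param pseudocount floor applied to the knockout mean, guarding empty
#'   knockout regions without perturbing exact ratios elsewhere.
#' @return A list with \code{A1} and \code{A2} (subsets of
#'   \code{open_sites}, each with \code{mean_wt}, \code{mean_ko} and
#'   \code{loss_ratio} metadata columns).
#' @export
classify_atac_loss <- function(open_sites, atac_wt_signal, atac_ko_signal,
                               ratio = 2, pseudocount = 0.01) {
  mean_wt <- track_means(atac_wt_signal, open_sites)
  mean_ko <- track_means(atac_ko_signal, open_sites)
  lr <- mean_wt / pmax(mean_ko, pseudocount)
  out <- open_sites
  out$mean_wt <- mean_wt; out$mean_ko <- mean_ko; out$loss_ratio <- lr
  list(A1 = out[lr >= ratio], A2 = out[lr < ratio])
}

#' Partition marked sites into H3K9ac lost (H1) vs retained (H2)
#'
#' A marked site retains H3K9ac (group H2) when it still overlaps a
#' knockout H3K9ac peak by at least 1 bp \emph{and} its WT/KO mean-signal
#' ratio stays below \code{ratio}; otherwise the mark is lost (group H1).
#' Either criterion can be disabled, making the rule peak-presence-only or
#' signal-ratio-only.
#'
#' @param marked_sites \code{GRanges} of marked ZCWPW1 sites.
#' @param h3k9ac_ko_peaks \code{GRanges} of knockout H3K9ac peaks (used when
#'   \code{use_peaks} is TRUE).
#' @param h3k9ac_wt_signal,h3k9ac_ko_signal \code{RleList} fold-change
#'   tracks (used when \code{use_ratio} is TRUE).
#' @param ratio loss threshold on WT/KO mean signal (inclusive for loss).
#' @param pseudocount floor applied to the knockout mean.
#' @param use_peaks,use_ratio enable each retention criterion.
#' @return A list with \code{H1} and \code{H2} subsets of
#'   \code{marked_sites}.
#' @export
classify_h3k9ac_loss <- function(marked_sites, h3k9ac_ko_peaks = NULL,
                                 h3k9ac_wt_signal = NULL,
                                 h3k9ac_ko_signal = NULL, ratio = 2,
                                 pseudocount = 0.01, use_peaks = TRUE,
                                 use_ratio = TRUE) {
  if (!use_peaks && !use_ratio)
    stop("at least one of use_peaks/use_ratio must be TRUE")
  retained <- rep(TRUE, length(marked_sites))
  out <- marked_sites
  if (use_peaks) {
    stopifnot(is(h3k9ac_ko_peaks, "GRanges"))
    has_ko_peak <- overlapsAny(marked_sites, h3k9ac_ko_peaks, minoverlap = 1L,
                               ignore.strand = TRUE)
    retained <- retained & has_ko_peak
  }
  if (use_ratio) {
    mean_wt <- track_means(h3k9ac_wt_signal, marked_sites)
    mean_ko <- track_means(h3k9ac_ko_signal, marked_sites)
    lr <- mean_wt / pmax(mean_ko, pseudocount)
    out$mean_wt <- mean_wt; out$mean_ko <- mean_ko; out$loss_ratio <- lr
    retained <- retained & (lr < ratio)
  }
  list(H1 = out[!retained], H2 = out[retained])
}

#' Joint loss of accessibility and acetylation
#'
#' The count and fraction of accessibility-lost (A1) sites that also lost
#' H3K9ac (H1); site identity is exact coordinates of the underlying ZCWPW1
#' peak.
#'
#' @param a1_sites,h1_sites \code{GRanges} subsets of the same ZCWPW1 peak
#'   set.
#' @return A list with \code{count} (size of the intersection) and
#'   \code{fraction} (count over |A1|; \code{NaN} when A1 is empty).
#' @export
joint_loss <- function(a1_sites, h1_sites) {
  ka <- site_ids(a1_sites); kh <- site_ids(h1_sites)
  n <- sum(ka %in% kh)
  list(count = n, fraction = if (length(ka)) n / length(ka) else NaN)
}

#' Annotate sites overlapping promoter windows
#'
#' A site is a promoter site when it overlaps, by at least 1 bp, the
#' strand-aware window from \code{upstream} bp before to \code{downstream}
#' bp after some transcription start site.
#'
#' @param sites \code{GRanges} of sites.
#' @param tss either a width-1 \code{GRanges} of TSS positions (with strand)
#'   or a data frame with columns \code{chrom}, \code{pos} (0-based) and
#'   \code{strand}.
#' @param upstream,downstream window extent in bp.
#' @return Logical vector parallel to \code{sites}.
#' @export
annotate_promoters <- function(sites, tss, upstream = 2000L,
                               downstream = 500L) {
  if (is.data.frame(tss)) {
    tss <- GRanges(tss$chrom, IRanges(tss$pos + 1L, width = 1L),
                   strand = tss$strand)
  }
  stopifnot(is(tss, "GRanges"))
  if (length(tss) == 0L) stop("TSS list is empty")
  win <- suppressWarnings(promoters(tss, upstream = upstream,
                                    downstream = downstream))
  win <- restrict_to_positive(win)
  overlapsAny(sites, win, minoverlap = 1L, ignore.strand = TRUE)
}

# Clip promoter windows at the chromosome start (coordinate 1).
restrict_to_positive <- function(gr) {
  s <- pmax(start(gr), 1L)
  e <- end(gr)
  keep <- e >= s
  gr <- gr[keep]
  start(gr) <- pmax(start(gr), 1L)
  gr
}

#' Classify reader binding sites end to end
#'
#' Applies, in order: the H3K9ac marking rule, the openness rule, the
#' acetylation and accessibility loss partitions, the joint-loss overlap and
#' promoter annotation, producing a per-site label table.
#'
#' @param zcwpw1 \code{GRanges} of ZCWPW1 binding sites (WT).
#' @param h3k9ac_wt,h3k9ac_ko,atac_wt \code{GRanges} peak sets.
#' @param h3k9ac_wt_signal,h3k9ac_ko_signal,atac_wt_signal,atac_ko_signal
#'   \code{RleList} fold-change tracks.
#' @param tss TSS annotation (see \code{\link{annotate_promoters}}).
#' @param atac_loss_ratio,h3k9ac_loss_ratio inclusive WT/KO loss thresholds.
#' @param open_frac inclusive openness fraction of the ATAC peak.
#' @param promoter_upstream,promoter_downstream promoter window in bp.
#' @param pseudocount floor on knockout means in loss ratios.
#' @return \code{zcwpw1} with added metadata columns: logical \code{marked},
#'   \code{open}, \code{promoter}; factor \code{h_group} (H1/H2, NA when
#'   unmarked) and \code{a_group} (A1/A2, NA when closed); numeric
#'   per-genotype mean signals where computed.
#' @export
classify_sites <- function(zcwpw1, h3k9ac_wt, h3k9ac_ko, atac_wt,
                           h3k9ac_wt_signal, h3k9ac_ko_signal,
                           atac_wt_signal, atac_ko_signal, tss,
                           atac_loss_ratio = 2, h3k9ac_loss_ratio = 2,
                           open_frac = 0.2, promoter_upstream = 2000L,
                           promoter_downstream = 500L, pseudocount = 0.01) {
  ids <- site_ids(zcwpw1)
  marked <- mark_h3k9ac(zcwpw1, h3k9ac_wt)
  open <- find_open_sites(zcwpw1, atac_wt, min_frac = open_frac)
  hpart <- classify_h3k9ac_loss(marked, h3k9ac_ko, h3k9ac_wt_signal,
                                h3k9ac_ko_signal, ratio = h3k9ac_loss_ratio,
                                pseudocount = pseudocount)
  apart <- classify_atac_loss(open, atac_wt_signal, atac_ko_signal,
                              ratio = atac_loss_ratio,
                              pseudocount = pseudocount)
  out <- zcwpw1
  out$marked <- ids %in% site_ids(marked)
  out$open <- ids %in% site_ids(open)
  h_group <- rep(NA_character_, length(out))
  h_group[ids %in% site_ids(hpart$H1)] <- "H1"
  h_group[ids %in% site_ids(hpart$H2)] <- "H2"
  a_group <- rep(NA_character_, length(out))
  a_group[ids %in% site_ids(apart$A1)] <- "A1"
  a_group[ids %in% site_ids(apart$A2)] <- "A2"
  out$h_group <- factor(h_group, levels = c("H1", "H2"))
  out$a_group <- factor(a_group, levels = c("A1", "A2"))
  out$h3k9ac_wt_mean <- track_means(h3k9ac_wt_signal, out)
  out$h3k9ac_ko_mean <- track_means(h3k9ac_ko_signal, out)
  out$atac_wt_mean <- track_means(atac_wt_signal, out)
  out$atac_ko_mean <- track_means(atac_ko_signal, out)
  out$promoter <- annotate_promoters(out, tss,
                                     upstream = promoter_upstream,
                                     downstream = promoter_downstream)
  out
}

# Round half away from zero to `digits` decimals (printed-report convention;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a classification report from counts
#'
#' Computes every percentage the classifier reports from its raw counts:
#' group fractions are printed as whole percents, promoter fractions with
#' one decimal, both rounded half up. The constructor enforces the partition
#' identities (marked = H1 + H2, open = A1 + A2, joint <= min(A1, H1)).
#'
#' @param n_sites total ZCWPW1 binding sites.
#' @param n_marked sites overlapping a WT H3K9ac peak.
#' @param n_h1,n_h2 marked sites that lost / retained H3K9ac in the
#'   knockout.
#' @param n_open sites overlapping at least 20\% of a WT ATAC peak.
#' @param n_a1,n_a2 open sites that lost / retained accessibility.
#' @param n_joint A1 sites that are also H1.
#' @param promoter_by_group optional named numeric vector of promoter-site
#'   counts per group (names among H1, H2, A1, A2).
#' @return A list of class \code{classification_report} with elements
#'   \code{counts} and \code{percent}.
#' @export
classification_report <- function(n_sites, n_marked, n_h1, n_h2, n_open,
                                  n_a1, n_a2, n_joint,
                                  promoter_by_group = NULL) {
  counts <- c(n_sites = n_sites, n_marked = n_marked, n_h1 = n_h1,
              n_h2 = n_h2, n_open = n_open, n_a1 = n_a1, n_a2 = n_a2,
              n_joint = n_joint)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_h1 + n_h2 != n_marked)
    stop("invariant violated: n_h1 + n_h2 != n_marked")
  if (n_a1 + n_a2 != n_open)
    stop("invariant violated: n_a1 + n_a2 != n_open")
  if (n_joint > min(n_a1, n_h1))
    stop("invariant violated: n_joint > min(n_a1, n_h1)")
  pct <- function(num, den) {
    if (den == 0) return(0)
    round_half_up(100 * num / den)
  }
  percent <- c(marked = pct(n_marked, n_sites),
               open = pct(n_open, n_sites),
               h1 = pct(n_h1, n_marked), h2 = pct(n_h2, n_marked),
               a1 = pct(n_a1, n_open), a2 = pct(n_a2, n_open),
               joint = pct(n_joint, n_a1))
  rep <- list(counts = counts, percent = percent)
  if (!is.null(promoter_by_group)) {
    den <- c(H1 = n_h1, H2 = n_h2, A1 = n_a1, A2 = n_a2)
    grp <- names(promoter_by_group)
    stopifnot(all(grp %in% names(den)))
    pp <- ifelse(den[grp] > 0,
                 round_half_up(100 * promoter_by_group / den[grp], 1L), 0)
    rep$promoter_counts <- promoter_by_group
    rep$promoter_percent <- setNames(as.numeric(pp), grp)
  }
  structure(rep, class = "classification_report")
}

#' Summarize per-site labels into the counts/percentages report
#'
#' @param labels the labelled \code{GRanges} returned by
#'   \code{\link{classify_sites}}.
#' @return A \code{\link{classification_report}}.
#' @export
summarize_classification <- function(labels) {
  h <- as.character(labels$h_group); a <- as.character(labels$a_group)
  jl <- joint_loss(labels[!is.na(a) & a == "A1"],
                   labels[!is.na(h) & h == "H1"])
  prom <- vapply(c(H1 = "H1", H2 = "H2"), function(g)
    sum(labels$promoter[!is.na(h) & h == g]), numeric(1))
  prom <- c(prom, vapply(c(A1 = "A1", A2 = "A2"), function(g)
    sum(labels$promoter[!is.na(a) & a == g]), numeric(1)))
  classification_report(
    n_sites = length(labels),
    n_marked = sum(labels$marked),
    n_h1 = sum(h == "H1", na.rm = TRUE),
    n_h2 = sum(h == "H2", na.rm = TRUE),
    n_open = sum(labels$open),
    n_a1 = sum(a == "A1", na.rm = TRUE),
    n_a2 = sum(a == "A2", na.rm = TRUE),
    n_joint = jl$count,
    promoter_by_group = prom)
}

#' @export
print.classification_report <- function(x, ...) {
  ct <- x$counts; pc <- x$percent
  cat("Site classification report\n")
  cat(sprintf("  sites: %d\n", ct[["n_sites"]]))
  cat(sprintf("  marked with H3K9ac: %d (%s%%)\n", ct[["n_marked"]],
              pc[["marked"]]))
  cat(sprintf("    H1 lost:     %d (%s%% of marked)\n", ct[["n_h1"]],
              pc[["h1"]]))
  cat(sprintf("    H2 retained: %d (%s%% of marked)\n", ct[["n_h2"]],
              pc[["h2"]]))
  cat(sprintf("  open (ATAC): %d (%s%%)\n", ct[["n_open"]], pc[["open"]]))
  cat(sprintf("    A1 lost:     %d (%s%% of open)\n", ct[["n_a1"]],
              pc[["a1"]]))
  cat(sprintf("    A2 retained: %d (%s%% of open)\n", ct[["n_a2"]],
              pc[["a2"]]))
  cat(sprintf("  joint loss (A1 & H1): %d (%s%% of A1)\n", ct[["n_joint"]],
              pc[["joint"]]))
  if (!is.null(x$promoter_percent)) {
    cat("  promoter fraction by group:",
        paste(sprintf("%s %.1f%%", names(x$promoter_percent),
                      x$promoter_percent), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write per-site labels and the report
#'
#' \code{write_labels} emits one TSV row per site (BED coordinates, group
#' labels, per-genotype means, promoter flag); \code{write_report} writes
#' the counts and percentages as JSON.
#'
#' @param labels labelled \code{GRanges} from \code{\link{classify_sites}}.
#' @param report a \code{classification_report}.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(chrom = as.character(seqnames(labels)),
                   start = start(labels) - 1L, end = end(labels),
                   as.data.frame(mcols(labels)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
write_report <- function(report, path) {
  out <- list(counts = as.list(report$counts),
              percent = as.list(report$percent))
  if (!is.null(report$promoter_percent))
    out$promoter_percent <- as.list(report$promoter_percent)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
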