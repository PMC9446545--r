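#' Run the full analysis pipeline on a simulated experiment
#'
#' Chains the stages of the study's computational analysis: simulate (or
#' accept) the genotype-specific tracks, call peaks per assay with the
#' matching preset, classify every ZCWPW1 binding site (H1/H2, A1/A2,
#' promoter), summarize, and score the predictions against the planted
#' truth.
#'
#' Peak calling uses the \code{zcwpw1_chip} preset for ZCWPW1, the
#' \code{h3k9ac_chip} preset for H3K9ac (WT and knockout) and the
#' \code{atac} preset for ATAC.
#'
#' @param config a \code{\link{sim_config}} describing the experiment.
#' @param outdir optional directory; when given, peaks (BED), labels (TSV),
#'   the report (JSON) and a run manifest are written there.
#' @param sim optional pre-computed result of
#'   \code{\link{simulate_experiment}} for this config (re-simulated when
#'   \code{NULL}).
#' @param verbose print per-stage progress messages.
#' @param ... extra arguments forwarded to \code{\link{classify_sites}}.
#' @return A list with \code{sim}, \code{peaks} (named list of peak sets),
#'   \code{labels}, \code{report}, \code{evaluation} (see
#'   \code{\link{evaluate_against_truth}}) and \code{manifest}.
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL, sim = NULL,
                         verbose = FALSE, ...) {
  say <- function(...) if (verbose) message("[chromcross] ", ...)
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(sim)) sim <- stage("simulate", simulate_experiment(config))
  layout <- sim$layout
  needed <- c("ZCWPW1.WT", "H3K9ac.WT", "H3K9ac.Zcwpw1KO", "ATAC.WT",
              "ATAC.Zcwpw1KO")
  missing <- setdiff(needed, names(sim$coverage))
  if (length(missing))
    stop("simulation lacks required tracks: ",
         paste(missing, collapse = ", "))
  peaks <- stage("callpeaks", list(
    zcwpw1 = call_peaks(sim$coverage[["ZCWPW1.WT"]], layout,
                        caller_preset("zcwpw1_chip"), "ZCWPW1", "WT"),
    h3k9ac_wt = call_peaks(sim$coverage[["H3K9ac.WT"]], layout,
                           caller_preset("h3k9ac_chip"), "H3K9ac", "WT"),
    h3k9ac_ko = call_peaks(sim$coverage[["H3K9ac.Zcwpw1KO"]], layout,
                           caller_preset("h3k9ac_chip"), "H3K9ac",
                           "Zcwpw1KO"),
    atac_wt = call_peaks(sim$coverage[["ATAC.WT"]], layout,
                         caller_preset("atac"), "ATAC", "WT")))
  labels <- stage("classify", classify_sites(
    peaks$zcwpw1, peaks$h3k9ac_wt, peaks$h3k9ac_ko, peaks$atac_wt,
    h3k9ac_wt_signal = sim$signal[["H3K9ac.WT"]],
    h3k9ac_ko_signal = sim$signal[["H3K9ac.Zcwpw1KO"]],
    atac_wt_signal = sim$signal[["ATAC.WT"]],
    atac_ko_signal = sim$signal[["ATAC.Zcwpw1KO"]],
    tss = sim$tss, ...))
  report <- stage("report", summarize_classification(labels))
  evaluation <- stage("evaluate", evaluate_against_truth(labels, sim$sites))
  manifest <- list(
    subcommand = "run-all", seed = sim$config$seed,
    n_hotspot_sites = sim$config$n_hotspot_sites,
    n_promoter_sites = sim$config$n_promoter_sites,
    package_version = as.character(packageVersion("chromcross")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (k in names(peaks))
      write_bed(peaks[[k]], file.path(outdir, paste0("peaks_", k, ".bed")))
    write_labels(labels, file.path(outdir, "site_labels.tsv"))
    write_report(report, file.path(outdir, "report.json"))
    manifest$outdir <- normalizePath(outdir)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("done: ", length(labels), " sites classified")
  list(sim = sim, peaks = peaks, labels = labels, report = report,
       evaluation = evaluation, manifest = manifest)
}

#' Score predicted site labels against planted truth
#'
#' Each truth site is matched to the called ZCWPW1 peak overlapping it most;
#' its predicted acetylation label (H1/H2/unmarked) and accessibility label
#' (A1/A2/closed) are compared with the planted ones. An unmatched truth
#' site counts as wrong on both axes.
#'
#' @param labels labelled \code{GRanges} from \code{\link{classify_sites}}.
#' @param truth_sites truth-annotated \code{GRanges} from
#'   \code{\link{simulate_experiment}} (\code{sim$sites}).
#' @return A list: \code{accuracy} (fraction of truth sites with both labels
#'   correct), \code{h_accuracy}, \code{a_accuracy}, \code{n_truth},
#'   \code{n_matched}, \code{n_unmatched_peaks} (called peaks touching no
#'   truth site), and the per-site comparison data frame \code{detail}.
#' @export
evaluate_against_truth <- function(labels, truth_sites) {
  hits <- findOverlaps(truth_sites, labels, ignore.strand = TRUE)
  pred_h <- rep(NA_character_, length(truth_sites))
  pred_a <- rep(NA_character_, length(truth_sites))
  if (length(hits)) {
    ov <- overlap_bp(truth_sites[queryHits(hits)], labels[subjectHits(hits)])
    best <- tapply(seq_along(ov), queryHits(hits),
                   function(i) subjectHits(hits)[i[which.max(ov[i])]])
    qi <- as.integer(names(best))
    h <- as.character(labels$h_group[as.integer(best)])
    a <- as.character(labels$a_group[as.integer(best)])
    marked <- labels$marked[as.integer(best)]
    open <- labels$open[as.integer(best)]
    pred_h[qi] <- ifelse(!marked, "unmarked", h)
    pred_a[qi] <- ifelse(!open, "closed", a)
  }
  h_ok <- !is.na(pred_h) & pred_h == truth_sites$h_label
  a_ok <- !is.na(pred_a) & pred_a == truth_sites$a_label
  detail <- data.frame(site_id = truth_sites$site_id,
                       truth_h = truth_sites$h_label, pred_h = pred_h,
                       truth_a = truth_sites$a_label, pred_a = pred_a,
                       stringsAsFactors = FALSE)
  list(accuracy = mean(h_ok & a_ok), h_accuracy = mean(h_ok),
       a_accuracy = mean(a_ok), n_truth = length(truth_sites),
       n_matched = sum(!is.na(pred_h)),
       n_unmatched_peaks = sum(!overlapsAny(labels, truth_sites,
                                            ignore.strand = TRUE)),
       detail = detail)
}
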