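#' Configuration of the synthetic experiment generator
#'
#' Describes a small multi-chromosome genome carrying two classes of planted
#' ZCWPW1 binding sites with known fates across four genotypes:
#' \describe{
#'   \item{hotspot}{recombination-hotspot-like sites with strong ZCWPW1,
#'     H3K9ac, ATAC and DMC1 enrichment in WT. In the \emph{Zcwpw1} knockout
#'     a designated fraction of the marked ones lose H3K9ac (group H1 truth)
#'     and of the open ones lose accessibility (group A1 truth); in the
#'     \emph{Prdm9} knockout all hotspot enrichment disappears; in the
#'     \emph{Spo11} knockout everything persists except DMC1.}
#'   \item{promoter}{TSS-centered sites whose H3K9ac and ATAC enrichment
#'     persist in every genotype (groups H2/A2 truth).}
#' }
#'
#' Loss assignments are planted as exact counts
#' (\code{round(loss_fraction * n_eligible)}), so the configured fractions
#' are the ground truth up to rounding rather than a sampling expectation.
#'
#' @param layout genome \code{Seqinfo}; default three 2-Mb chromosomes.
#' @param n_hotspot_sites,n_promoter_sites planted site counts per class.
#' @param n_extra_tss additional TSS placed away from planted sites, so the
#'   promoter annotation has realistic background.
#' @param site_width planted site width in bp (snapped to the simulation
#'   cell grid).
#' @param background_rate background fragment coverage in reads per bp.
#' @param enrichment matrix of WT fold enrichment over background, assays in
#'   rows (ZCWPW1, H3K9ac, ATAC, DMC1), site classes in columns (hotspot,
#'   promoter). A value of 0 means the assay is absent from that class.
#' @param hotspot_marked_frac fraction of hotspot sites carrying H3K9ac in
#'   WT (the rest are unmarked truth).
#' @param hotspot_open_frac fraction of hotspot sites carrying ATAC signal
#'   in WT (the rest are closed truth).
#' @param loss_fraction named vector: fraction of \emph{all} marked sites
#'   that lose H3K9ac (\code{H3K9ac}) and of all open sites that lose
#'   accessibility (\code{ATAC}) in the \emph{Zcwpw1} knockout. Losses are
#'   assigned only to hotspot-class sites, so each fraction must not exceed
#'   the hotspot share of the eligible set.
#' @param loss_multiplier residual enrichment multiplier at losing sites
#'   (<= 0.3: a strong but not necessarily complete loss).
#' @param assays,genotypes subsets to simulate (all by default).
#' @param cell simulation resolution in bp: coverage is drawn per cell from
#'   a Poisson law and expanded.
#' @param min_site_gap minimum distance between planted sites in bp.
#' @param seed integer root seed; all outputs are pure functions of the
#'   configuration including the seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(layout = genome_layout(paste0("chr", 1:3),
                                              rep(2e6, 3)),
                       n_hotspot_sites = 200L, n_promoter_sites = 40L,
                       n_extra_tss = 100L, site_width = 600L,
                       background_rate = 0.05,
                       enrichment = default_enrichment(),
                       hotspot_marked_frac = 0.85,
                       hotspot_open_frac = 0.45,
                       loss_fraction = c(H3K9ac = 0.74, ATAC = 0.67),
                       loss_multiplier = 0.2,
                       assays = c("ZCWPW1", "H3K9ac", "ATAC", "DMC1"),
                       genotypes = c("WT", "Zcwpw1KO", "Prdm9KO",
                                     "Spo11KO"),
                       cell = 10L, min_site_gap = 2000L, seed = 42L) {
  stopifnot(is(layout, "Seqinfo"))
  n_sites <- n_hotspot_sites + n_promoter_sites
  if (n_sites * site_width >= sum(as.numeric(seqlengths(layout))) / 2)
    stop("planted sites would cover more than half the genome")
  stopifnot(all(enrichment >= 0), background_rate > 0,
            loss_multiplier >= 0,
            all(loss_fraction >= 0 & loss_fraction <= 1),
            all(c("H3K9ac", "ATAC") %in% names(loss_fraction)),
            site_width %% cell == 0L)
  structure(list(layout = layout, n_hotspot_sites = as.integer(n_hotspot_sites),
                 n_promoter_sites = as.integer(n_promoter_sites),
                 n_extra_tss = as.integer(n_extra_tss),
                 site_width = as.integer(site_width),
                 background_rate = background_rate, enrichment = enrichment,
                 hotspot_marked_frac = hotspot_marked_frac,
                 hotspot_open_frac = hotspot_open_frac,
                 loss_fraction = loss_fraction,
                 loss_multiplier = loss_multiplier, assays = assays,
                 genotypes = genotypes, cell = as.integer(cell),
                 min_site_gap = as.integer(min_site_gap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_enrichment <- function() {
  matrix(c(10, 5,   # ZCWPW1: strong at hotspots, weaker at promoter sites
           8, 8,    # H3K9ac
           8, 8,    # ATAC
           10, 0),  # DMC1: hotspot-specific
         nrow = 4, byrow = TRUE,
         dimnames = list(c("ZCWPW1", "H3K9ac", "ATAC", "DMC1"),
                         c("hotspot", "promoter")))
}

# Deterministic child seed per coverage track, so adding an assay or
# genotype never perturbs the draws of another track.
track_seed <- function(seed, index) {
  (abs(seed) %% 80000000L) * 25L + index
}

#' Simulate a full multi-genotype chromatin experiment
#'
#' Places non-overlapping sites uniformly at random (snapped to the cell
#' grid), draws Poisson coverage per cell for every requested assay x
#' genotype track, derives fold-change signal tracks over the known
#' background rate, and returns everything together with the ground-truth
#' label table.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with elements \code{config}, \code{layout}, \code{sites}
#'   (truth-annotated \code{GRanges}), \code{truth} (the same as a data
#'   frame), \code{tss} (width-1 \code{GRanges}), \code{coverage} and
#'   \code{signal} (named lists \code{"<assay>.<genotype>"} of
#'   \code{RleList} tracks).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  set.seed(config$seed)
  sites <- place_sites(config)
  truth <- assign_truth(sites, config)
  tss <- make_tss(truth, config)
  truth$promoter_truth <- annotate_promoters(truth, tss)

  combos <- expand.grid(assay = config$assays, genotype = config$genotypes,
                        stringsAsFactors = FALSE)
  coverage <- vector("list", nrow(combos))
  names(coverage) <- paste(combos$assay, combos$genotype, sep = ".")
  for (k in seq_len(nrow(combos))) {
    set.seed(track_seed(config$seed, k))
    coverage[[k]] <- simulate_track(combos$assay[k], combos$genotype[k],
                                    truth, config)
  }
  signal <- lapply(coverage, normalize_fold_change,
                   control = config$background_rate,
                   pseudocount = config$background_rate)
  list(config = config, layout = layout, sites = truth,
       truth = truth_table(truth), tss = tss, coverage = coverage,
       signal = signal)
}

# Uniform non-overlapping placement on the cell grid, bounded retries.
place_sites <- function(config) {
  layout <- config$layout
  w <- config$site_width
  gap <- config$min_site_gap
  n <- config$n_hotspot_sites + config$n_promoter_sites
  lens <- as.numeric(seqlengths(layout))
  placed <- GRanges(seqinfo = layout)
  tries <- 0L
  while (length(placed) < n) {
    if (tries > 200L * n)
      stop("could not place ", n, " non-overlapping sites; ",
           "genome too small for the requested density")
    tries <- tries + 1L
    ci <- sample.int(length(lens), 1L, prob = lens)
    chrom <- seqnames(layout)[ci]
    max_cell <- (lens[ci] - w - 2L * gap) %/% config$cell
    s <- (sample.int(max_cell, 1L) + gap %/% config$cell) * config$cell + 1L
    cand <- GRanges(chrom, IRanges(s, width = w), seqinfo = layout)
    ok <- TRUE
    if (length(placed) > 0L) {
      h <- distanceToNearest(cand, placed, ignore.strand = TRUE)
      ok <- length(h) == 0L || mcols(h)$distance >= gap
    }
    if (ok) placed <- c(placed, cand)
  }
  sort(sortSeqlevels(placed), ignore.strand = TRUE)
}

# Plant the class structure and the exact-count loss assignments.
assign_truth <- function(sites, config) {
  n <- length(sites)
  nh <- config$n_hotspot_sites
  cls <- rep("promoter", n)
  cls[sample.int(n, nh)] <- "hotspot"
  hot <- which(cls == "hotspot")
  marked <- cls == "promoter"   # promoter sites always marked and open
  open <- cls == "promoter"
  marked[sample(hot, round_half_up(config$hotspot_marked_frac * nh))] <- TRUE
  open[sample(hot, round_half_up(config$hotspot_open_frac * nh))] <- TRUE

  n_h1 <- round_half_up(config$loss_fraction[["H3K9ac"]] * sum(marked))
  eligible_h <- which(marked & cls == "hotspot")
  if (n_h1 > length(eligible_h))
    stop("loss_fraction['H3K9ac'] = ", config$loss_fraction[["H3K9ac"]],
         " exceeds the hotspot share of marked sites (",
         length(eligible_h), "/", sum(marked), ")")
  h_lost <- rep(FALSE, n)
  h_lost[sample(eligible_h, n_h1)] <- TRUE

  n_a1 <- round_half_up(config$loss_fraction[["ATAC"]] * sum(open))
  eligible_a <- which(open & cls == "hotspot")
  if (n_a1 > length(eligible_a))
    stop("loss_fraction['ATAC'] = ", config$loss_fraction[["ATAC"]],
         " exceeds the hotspot share of open sites (",
         length(eligible_a), "/", sum(open), ")")
  a_lost <- rep(FALSE, n)
  a_lost[sample(eligible_a, n_a1)] <- TRUE

  out <- sites
  out$site_id <- sprintf("site_%04d", seq_len(n))
  out$class <- cls
  out$marked_truth <- marked
  out$open_truth <- open
  out$h_label <- ifelse(!marked, "unmarked", ifelse(h_lost, "H1", "H2"))
  out$a_label <- ifelse(!open, "closed", ifelse(a_lost, "A1", "A2"))
  out
}

# TSS at every promoter-class site center plus random extra TSS.
make_tss <- function(truth, config) {
  layout <- config$layout
  prom <- truth[truth$class == "promoter"]
  centers <- (start(prom) + end(prom)) %/% 2L
  tss <- GRanges(seqnames(prom), IRanges(centers, width = 1L),
                 strand = sample(c("+", "-"), length(prom), replace = TRUE),
                 seqinfo = layout)
  if (config$n_extra_tss > 0L) {
    lens <- as.numeric(seqlengths(layout))
    ci <- sample.int(length(lens), config$n_extra_tss, replace = TRUE,
                     prob = lens)
    pos <- floor(runif(config$n_extra_tss, min = 1, max = lens[ci]))
    extra <- GRanges(seqnames(layout)[ci], IRanges(pos, width = 1L),
                     strand = sample(c("+", "-"), config$n_extra_tss,
                                     replace = TRUE),
                     seqinfo = layout)
    tss <- c(tss, extra)
  }
  sort(sortSeqlevels(tss), ignore.strand = TRUE)
}

# Enrichment multiplier of one site for one assay and genotype. The rate at
# a site is background * max(1, enrichment * multiplier): genotype effects
# scale the enrichment component and the antibody/transposase background
# floor always remains.
genotype_multiplier <- function(assay, genotype, site) {
  if (genotype == "WT") return(1)
  if (genotype == "Spo11KO") return(if (assay == "DMC1") 0 else 1)
  if (genotype == "Prdm9KO")
    return(if (site$class == "hotspot") 0 else 1)
  # Zcwpw1KO
  if (assay == "ZCWPW1") return(0)
  if (assay == "H3K9ac" && site$h_label == "H1") return(NA) # loss_multiplier
  if (assay == "ATAC" && site$a_label == "A1") return(NA)
  1
}

simulate_track <- function(assay, genotype, truth, config) {
  layout <- config$layout
  cell <- config$cell
  bg_cell <- config$background_rate * cell
  sn <- as.character(seqnames(truth))
  tracks <- lapply(seqnames(layout), function(chrom) {
    L <- seqlengths(layout)[[chrom]]
    ncell <- L %/% cell
    rate <- rep(bg_cell, ncell)
    for (i in which(sn == chrom)) {
      site <- truth[i]
      e <- config$enrichment[assay, site$class]
      # absence of the mark in WT (unmarked/closed truth) zeroes enrichment
      if (assay == "H3K9ac" && !site$marked_truth) e <- 0
      if (assay == "ATAC" && !site$open_truth) e <- 0
      m <- genotype_multiplier(assay, genotype, site)
      if (is.na(m)) m <- config$loss_multiplier
      mult <- max(1, e * m)
      c1 <- (start(site) - 1L) %/% cell + 1L
      c2 <- min(ncell, (end(site) - 1L) %/% cell + 1L)
      rate[c1:c2] <- bg_cell * mult
    }
    draws <- rpois(ncell, rate)
    r <- Rle(rep(draws / cell, each = cell))
    tail_len <- L - ncell * cell
    if (tail_len > 0L) r <- c(r, Rle(0, tail_len))
    r
  })
  as(setNames(tracks, seqnames(layout)), "RleList")
}

# Flat data.frame view of the truth-annotated sites.
truth_table <- function(truth) {
  data.frame(site_id = truth$site_id,
             chrom = as.character(seqnames(truth)),
             start = start(truth) - 1L, end = end(truth),
             class = truth$class, marked = truth$marked_truth,
             open = truth$open_truth, h_label = truth$h_label,
             a_label = truth$a_label,
             promoter = truth$promoter_truth,
             stringsAsFactors = FALSE)
}

#' Write a simulated experiment to a directory
#'
#' Emits one bedGraph per coverage and signal track, the truth table, TSS
#' annotation, chrom sizes and the resolved configuration, mirroring the
#' on-disk layout a real experiment would arrive in.
#'
#' @param sim result of \code{\link{simulate_experiment}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(sim$layout, file.path(dir, "genome.chrom.sizes"))
  for (k in names(sim$coverage))
    write_bedgraph(sim$coverage[[k]],
                   file.path(dir, paste0("coverage_", k, ".bedgraph")))
  for (k in names(sim$signal))
    write_bedgraph(sim$signal[[k]],
                   file.path(dir, paste0("signal_", k, ".bedgraph")))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tss_df <- data.frame(chrom = as.character(seqnames(sim$tss)),
                       pos = start(sim$tss) - 1L,
                       strand = as.character(strand(sim$tss)))
  write.table(tss_df, file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- sim$config
  cfg_out <- cfg[setdiff(names(cfg), "layout")]
  cfg_out$enrichment <- as.data.frame(cfg$enrichment)
  cfg_out$chroms <- as.character(seqnames(cfg$layout))
  cfg_out$chrom_lengths <- unname(seqlengths(cfg$layout))
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic RIME evidence table with known truth
#'
#' True interactors receive, in at least one replicate, target-pulldown
#' evidence passing every filter criterion and never appear in IgG;
#' background proteins either fail at least one criterion in all replicates
#' or (a \code{contamination_rate} share of them) carry passing target
#' evidence but are also identified in the batch-matched IgG control.
#'
#' @param n_true_interactors,n_background protein counts.
#' @param contamination_rate fraction of background proteins routed through
#'   the IgG-contamination mode.
#' @param seed integer seed.
#' @param replicates replicate identifiers.
#' @return A list with \code{evidence} (data frame in the canonical layout)
#'   and \code{truth} (character vector of true-interactor ids).
#' @export
make_rime_table <- function(n_true_interactors = 40L, n_background = 160L,
                            contamination_rate = 0.2, seed = 1L,
                            replicates = c("Rep1", "Rep2", "Rep3")) {
  stopifnot(n_true_interactors >= 0, n_background >= 0,
            contamination_rate >= 0, contamination_rate <= 1)
  set.seed(as.integer(seed))
  nr <- length(replicates)
  rows <- list()
  add <- function(protein, rep, ab, batch, lgp, uniq, spec) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein_id = protein, replicate_id = rep, antibody = ab,
      batch = batch, neg10lgP = lgp, unique_peptides = uniq,
      spectral_counts = spec, stringsAsFactors = FALSE)
  }
  batch_of <- function(rep) paste0("batch_", rep)
  true_ids <- sprintf("TRUE%04d", seq_len(n_true_interactors))
  for (p in true_ids) {
    present <- runif(nr) < 0.8
    if (!any(present)) present[sample.int(nr, 1L)] <- TRUE
    for (j in which(present)) {
      add(p, replicates[j], "target", batch_of(replicates[j]),
          20 + rexp(1, 1 / 15), sample(1:10, 1L), sample(5:60, 1L))
    }
  }
  bg_ids <- sprintf("BG%04d", seq_len(n_background))
  n_contam <- round(contamination_rate * n_background)
  contam <- seq_len(n_background) <= n_contam
  for (i in seq_len(n_background)) {
    p <- bg_ids[i]
    present <- runif(nr) < 0.6
    if (!any(present)) present[sample.int(nr, 1L)] <- TRUE
    if (contam[i]) {
      # passes the scores but is seen in IgG of the same batch
      for (j in which(present))
        add(p, replicates[j], "target", batch_of(replicates[j]),
            20 + rexp(1, 1 / 10), sample(1:5, 1L), sample(5:30, 1L))
      jg <- which(present)
      for (j in jg)
        add(p, replicates[j], "IgG", batch_of(replicates[j]),
            rexp(1, 1 / 10), sample(0:3, 1L), sample(1:10, 1L))
    } else {
      mode <- sample(c("score", "unique", "spectra"), 1L)
      for (j in which(present)) {
        lgp <- if (mode == "score") runif(1, 0, 19.9) else 20 + rexp(1, 1 / 10)
        uniq <- if (mode == "unique") 0L else sample(1:5, 1L)
        spec <- if (mode == "spectra") sample(0:4, 1L) else sample(5:30, 1L)
        add(p, replicates[j], "target", batch_of(replicates[j]), lgp, uniq,
            spec)
      }
    }
  }
  evidence <- do.call(rbind, rows)
  list(evidence = evidence, truth = true_ids)
}
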