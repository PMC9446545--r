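test_that("simulation output is a pure function of config and seed", {
  cfg <- test_sim_config(seed = 5L, assays = c("ZCWPW1", "H3K9ac"),
                         genotypes = c("WT", "Zcwpw1KO"))
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$coverage, as.list),
                   lapply(s2$coverage, as.list))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bedgraph(s1$coverage[["ZCWPW1.WT"]], f1)
  write_bedgraph(s2$coverage[["ZCWPW1.WT"]], f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the draws
  s3 <- simulate_experiment(test_sim_config(seed = 6L,
                                            assays = c("ZCWPW1", "H3K9ac"),
                                            genotypes = c("WT", "Zcwpw1KO")))
  expect_false(identical(as.numeric(s3$coverage[["ZCWPW1.WT"]][["chr1"]]),
                         as.numeric(s1$coverage[["ZCWPW1.WT"]][["chr1"]])))
})

test_that("planted truth respects the configured class structure", {
  cfg <- test_sim_config(seed = 23L, assays = "ZCWPW1", genotypes = "WT")
  sim <- simulate_experiment(cfg)
  tt <- sim$truth
  expect_equal(nrow(tt), 38L)
  expect_equal(sum(tt$class == "hotspot"), 30L)
  # promoter-class sites are always marked, open and retained
  prom <- tt[tt$class == "promoter", ]
  expect_true(all(prom$marked & prom$open))
  expect_true(all(prom$h_label == "H2" & prom$a_label == "A2"))
  expect_true(all(prom$promoter))
  # losses are planted as exact rounded counts over the eligible sets
  expect_equal(sum(tt$h_label == "H1"), round(0.74 * sum(tt$marked)))
  expect_equal(sum(tt$a_label == "A1"), round(0.67 * sum(tt$open)))
  # sites do not overlap and keep their configured width
  gr <- GRanges(tt$chrom, IRanges(tt$start + 1, tt$end))
  expect_true(all(width(gr) == cfg$site_width))
  expect_equal(sum(countOverlaps(gr, gr) > 1), 0L)
})

test_that("background coverage matches the configured rate", {
  cfg <- test_sim_config(seed = 11L, assays = "ATAC", genotypes = "WT")
  sim <- simulate_experiment(cfg)
  track <- sim$coverage[["ATAC.WT"]]
  sites <- GRanges(sim$truth$chrom, IRanges(sim$truth$start + 1,
                                            sim$truth$end))
  for (chrom in names(track)) {
    mask <- rep(TRUE, length(track[[chrom]]))
    for (i in which(sim$truth$chrom == chrom))
      mask[sim$truth$start[i]:sim$truth$end[i]] <- FALSE
    v <- as.numeric(track[[chrom]])[mask]
    ncell <- sum(mask) / cfg$cell
    se <- sqrt(cfg$background_rate / (cfg$cell * ncell))
    expect_lt(abs(mean(v) - cfg$background_rate), 3 * se)
  }
})

test_that("planted signal means scale linearly with enrichment", {
  mk <- function(e) {
    enr <- default_enrichment(); enr["ATAC", "hotspot"] <- e
    cfg <- test_sim_config(seed = 19L, assays = "ATAC", genotypes = "WT",
                           enrichment = enr)
    sim <- simulate_experiment(cfg)
    hot <- sim$sites[sim$sites$class == "hotspot" & sim$sites$open_truth]
    mean(track_means(sim$coverage[["ATAC.WT"]], hot))
  }
  m4 <- mk(4); m8 <- mk(8)
  expect_equal(m8 / m4, 2, tolerance = 0.05)
})

test_that("with no planted enrichment the caller finds ~nothing", {
  enr <- default_enrichment(); enr[] <- 1
  cfg <- test_sim_config(seed = 29L, assays = "ATAC", genotypes = "WT",
                         enrichment = enr)
  sim <- simulate_experiment(cfg)
  peaks <- call_peaks(sim$coverage[["ATAC.WT"]], sim$layout,
                      caller_preset("h3k9ac_chip"))
  expect_lte(length(peaks), 1L)
})

test_that("synthetic RIME tables agree with an independent row-wise filter", {
  tab <- make_rime_table(n_true_interactors = 40, n_background = 160,
                         contamination_rate = 0.2, seed = 7)
  pos <- filter_evidence(tab$evidence)
  # clean recovery: the union of positives is exactly the planted truth
  expect_setequal(unique(unlist(pos)), tab$truth)
  # independent re-check, row by row, without the package's vector logic
  ev <- tab$evidence
  igg <- unique(paste(ev$protein_id[ev$antibody == "IgG"],
                      ev$batch[ev$antibody == "IgG"]))
  for (r in names(pos)) {
    manual <- character(0)
    for (i in seq_len(nrow(ev))) {
      row <- ev[i, ]
      if (row$antibody == "target" && row$replicate_id == r &&
          row$neg10lgP >= 20 && row$unique_peptides >= 1 &&
          row$spectral_counts >= 5 &&
          !(paste(row$protein_id, row$batch) %in% igg))
        manual <- c(manual, row$protein_id)
    }
    expect_setequal(pos[[r]], unique(manual))
  }
  # contamination_rate = 0 leaves no IgG rows at all
  clean <- make_rime_table(20, 50, contamination_rate = 0, seed = 2)
  expect_false(any(clean$evidence$antibody == "IgG"))
  expect_setequal(unique(unlist(filter_evidence(clean$evidence))),
                  clean$truth)
  # placing every protein in IgG empties the positives
  allg <- tab$evidence
  extra <- unique(allg[c("protein_id", "batch")])
  igg_rows <- data.frame(protein_id = extra$protein_id,
                         replicate_id = "Rep1", antibody = "IgG",
                         batch = extra$batch, neg10lgP = 5,
                         unique_peptides = 1, spectral_counts = 1)
  expect_equal(sum(lengths(filter_evidence(rbind(allg, igg_rows)))), 0L)
})

test_that("write_simulation emits a complete plain-text run directory", {
  cfg <- test_sim_config(seed = 3L, assays = "ZCWPW1", genotypes = "WT")
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "genome.chrom.sizes")))
  expect_true(file.exists(file.path(dir, "coverage_ZCWPW1.WT.bedgraph")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "tss.tsv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_bedgraph(file.path(dir, "coverage_ZCWPW1.WT.bedgraph"),
                        sim$layout)
  expect_equal(as.numeric(back[["chr1"]]),
               as.numeric(sim$coverage[["ZCWPW1.WT"]][["chr1"]]),
               tolerance = 1e-9)
})
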