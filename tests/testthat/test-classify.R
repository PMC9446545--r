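# Build a constant-valued track with rectangular bumps: bumps is a list of
# list(chrom, s, e, value) in 1-based closed coordinates.
bump_track <- function(layout, base = 0, bumps = list()) {
  tr <- as(setNames(lapply(seqlengths(layout), function(L) Rle(base, L)),
                    seqnames(layout)), "RleList")
  for (b in bumps) tr[[b$chrom]][b$s:b$e] <- b$value
  tr
}

g <- function(s0, e0, chrom = "chr1", layout = NULL) {
  gr <- GRanges(chrom, IRanges(s0 + 1, e0))
  if (!is.null(layout)) seqinfo(gr) <- layout
  gr
}

test_that("the 1-bp marking rule follows half-open arithmetic", {
  zcw <- c(g(100, 300), g(500, 700))
  expect_equal(length(mark_h3k9ac(zcw, g(299, 400))), 1L)  # 1-bp overlap
  expect_equal(length(mark_h3k9ac(zcw, g(300, 400))), 0L)  # abutting
})

test_that("openness requires >= 20% of a single ATAC peak", {
  expect_length(find_open_sites(g(0, 1000), g(800, 1800)), 1L)  # exactly 20%
  expect_length(find_open_sites(g(0, 100), g(50, 1050)), 0L)    # 5%
  # fractions never sum across partners: two 10% overlaps do not qualify
  atac <- c(g(900, 1900), g(-100 + 100, 100))  # second covers [0,100)
  site <- g(0, 1000)
  expect_length(find_open_sites(site, c(g(900, 1900), g(0, 1000 + 9000))), 0L)
  # measuring the fraction on the site instead is available behind the switch
  expect_length(find_open_sites(g(0, 100), g(50, 1050), frac_of = "site"),
                1L)  # 50 bp = 50% of the site
})

test_that("accessibility loss uses an inclusive 2-fold WT/KO ratio", {
  layout <- genome_layout("chr1", 10000)
  site <- g(1000, 1400, layout = layout)
  mk <- function(wt, ko) {
    list(wt = bump_track(layout, 0, list(list(chrom = "chr1", s = 1001,
                                              e = 1400, value = wt))),
         ko = bump_track(layout, 0, list(list(chrom = "chr1", s = 1001,
                                              e = 1400, value = ko))))
  }
  tr <- mk(4, 1)
  part <- classify_atac_loss(site, tr$wt, tr$ko)
  expect_length(part$A1, 1L); expect_length(part$A2, 0L)
  tr <- mk(2, 1.5)
  part <- classify_atac_loss(site, tr$wt, tr$ko)
  expect_length(part$A1, 0L); expect_length(part$A2, 1L)
  tr <- mk(2, 1)  # ratio exactly 2: "at least 2-fold" is inclusive
  part <- classify_atac_loss(site, tr$wt, tr$ko)
  expect_length(part$A1, 1L)
})

test_that("H3K9ac retention needs a knockout peak AND a stable ratio", {
  layout <- genome_layout("chr1", 10000)
  site <- g(1000, 1400, layout = layout)
  wt <- bump_track(layout, 0, list(list(chrom = "chr1", s = 1001, e = 1400,
                                        value = 2.2)))
  ko_same <- wt
  ko_low <- bump_track(layout, 0, list(list(chrom = "chr1", s = 1001,
                                            e = 1400, value = 0.5)))
  # no KO peak overlap: lost regardless of signal
  part <- classify_h3k9ac_loss(site, GRanges(), wt, ko_same)
  expect_length(part$H1, 1L)
  # KO peak present and ratio ~1: retained
  part <- classify_h3k9ac_loss(site, g(900, 1500), wt, ko_same)
  expect_length(part$H2, 1L)
  # KO peak present but >= 2-fold drop: lost
  part <- classify_h3k9ac_loss(site, g(900, 1500), wt, ko_low)
  expect_length(part$H1, 1L)
  # each criterion can be disabled
  part <- classify_h3k9ac_loss(site, GRanges(), wt, ko_same,
                               use_peaks = FALSE)
  expect_length(part$H2, 1L)
  part <- classify_h3k9ac_loss(site, g(900, 1500), use_ratio = FALSE)
  expect_length(part$H2, 1L)
  expect_error(classify_h3k9ac_loss(site, use_peaks = FALSE,
                                    use_ratio = FALSE), "at least one")
})

test_that("raising the loss ratio threshold never grows the lost groups", {
  layout <- genome_layout("chr1", 1e5)
  set.seed(13)
  sites <- GRanges("chr1", IRanges(seq(1001, 90001, by = 3000), width = 400),
                   seqinfo = layout)
  wt <- bump_track(layout, 0.2, lapply(seq_along(sites), function(i)
    list(chrom = "chr1", s = start(sites)[i], e = end(sites)[i],
         value = runif(1, 0.5, 6))))
  ko <- bump_track(layout, 0.2, lapply(seq_along(sites), function(i)
    list(chrom = "chr1", s = start(sites)[i], e = end(sites)[i],
         value = runif(1, 0.5, 6))))
  n2 <- length(classify_atac_loss(sites, wt, ko, ratio = 2)$A1)
  n3 <- length(classify_atac_loss(sites, wt, ko, ratio = 3)$A1)
  expect_lte(n3, n2)
  h2 <- length(classify_h3k9ac_loss(sites, sites, wt, ko, ratio = 2)$H1)
  h3 <- length(classify_h3k9ac_loss(sites, sites, wt, ko, ratio = 3)$H1)
  expect_lte(h3, h2)
})

test_that("joint loss counts the A1 sites that are also H1", {
  a1 <- c(g(0, 100), g(200, 300), g(400, 500))
  expect_equal(joint_loss(a1, a1)$fraction, 1)          # subset
  expect_equal(joint_loss(a1, g(900, 1000))$fraction, 0) # disjoint
  jl <- joint_loss(a1, c(g(0, 100), g(400, 500), g(700, 800)))
  expect_equal(jl$count, 2L)
  expect_equal(jl$fraction, 2 / 3)
})

test_that("promoter windows are strand-aware TSS neighborhoods", {
  layout <- genome_layout("chr1", 1e5)
  tss <- data.frame(chrom = "chr1", pos = c(50000, 20000),
                    strand = c("+", "-"))
  # site containing a TSS
  expect_true(annotate_promoters(g(49900, 50100, layout = layout), tss))
  # site 10 kb away with a 2-kb window
  expect_false(annotate_promoters(g(60000, 60200, layout = layout), tss))
  # upstream on the minus strand lies to the right of the TSS
  expect_true(annotate_promoters(g(21000, 21200, layout = layout), tss,
                                 upstream = 2000, downstream = 500))
  expect_false(annotate_promoters(g(21000, 21200, layout = layout), tss,
                                  upstream = 500, downstream = 500))
})

test_that("the report reproduces printed-style percentages from counts", {
  rep <- classification_report(n_sites = 14688, n_marked = 6627,
                               n_h1 = 4886, n_h2 = 1741, n_open = 4015,
                               n_a1 = 2676, n_a2 = 1339, n_joint = 2250)
  expect_equal(rep$percent[["h1"]], 74)
  expect_equal(rep$percent[["a1"]], 67)
  expect_equal(rep$percent[["marked"]], 45)
  expect_equal(rep$percent[["joint"]], 84)
  # rounding is half-up at the printed precision
  rep2 <- classification_report(10, 8, 2, 6, 4, 2, 2, 1)
  expect_equal(rep2$percent[["h1"]], 25)
  expect_error(classification_report(10, 8, 3, 6, 4, 2, 2, 1),
               "n_h1 \\+ n_h2")
  expect_error(classification_report(10, 8, 2, 6, 4, 2, 2, 3), "n_joint")
})

test_that("an empty site list yields an all-zero report without errors", {
  layout <- genome_layout("chr1", 1e4)
  empty <- GRanges(seqinfo = layout)
  empty$marked <- logical(0); empty$open <- logical(0)
  empty$h_group <- factor(character(0), levels = c("H1", "H2"))
  empty$a_group <- factor(character(0), levels = c("A1", "A2"))
  empty$promoter <- logical(0)
  rep <- summarize_classification(empty)
  expect_true(all(rep$counts == 0))
  expect_true(all(rep$percent == 0))
})

test_that("classify_sites recovers planted truth on simulated data", {
  cfg <- test_sim_config(seed = 101L,
                         assays = c("ZCWPW1", "H3K9ac", "ATAC"),
                         genotypes = c("WT", "Zcwpw1KO"))
  sim <- simulate_experiment(cfg)
  # classify the planted sites directly (peak calling is tested elsewhere)
  truth <- sim$sites
  marked <- mark_h3k9ac(truth, truth[truth$marked_truth])
  expect_setequal(site_ids_test(marked),
                  site_ids_test(truth[truth$marked_truth]))
  hpart <- classify_h3k9ac_loss(
    truth[truth$marked_truth],
    truth[truth$h_label == "H2"],
    sim$signal[["H3K9ac.WT"]], sim$signal[["H3K9ac.Zcwpw1KO"]])
  expect_setequal(site_ids_test(hpart$H1),
                  site_ids_test(truth[truth$h_label == "H1"]))
  apart <- classify_atac_loss(truth[truth$open_truth],
                              sim$signal[["ATAC.WT"]],
                              sim$signal[["ATAC.Zcwpw1KO"]])
  expect_setequal(site_ids_test(apart$A1),
                  site_ids_test(truth[truth$a_label == "A1"]))
  # partition completeness
  expect_equal(length(hpart$H1) + length(hpart$H2), sum(truth$marked_truth))
  expect_equal(length(apart$A1) + length(apart$A2), sum(truth$open_truth))
})
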