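# shared simulated map/genotype scaffold for the scan tests (built once)
scan_fixture <- local({
  env <- new.env()
  function() {
    if (!is.null(env$fix)) return(env$fix)
    cfg <- sim_config(n_progeny = 176, n_chrom = 2, snps_per_chrom = 900,
                      chrom_len_bp = 7.5e6, chrom_len_cM = 80,
                      error_rate = 0.01, missing_rate = 0.05, seed = 3)
    pop <- simulate_population(cfg)
    flt <- filter_sites(segregation_chi2(classify_segregation(
      mask_low_confidence(as_snp_data(pop)))))
    bins <- bin_markers(flt$sites)
    maps <- build_parental_maps(bins)
    cons <- merge_consensus(maps$maternal, maps$paternal, bins = bins)
    probs <- transmission_probs(cons, bins, eps = 0.01)
    env$fix <- list(pop = pop, bins = bins, map = cons, probs = probs)
    env$fix
  }
})

test_that("adjusted moments and paired statistics match hand values", {
  ts <- trait_stats(c(1, 2, 3, 4, 5))
  expect_equal(ts$skewness, 0)
  expect_equal(ts$kurtosis, -1.2)
  x <- rnorm(30)
  ts2 <- trait_stats(x, paired = x)
  expect_equal(ts2$pearson_r, 1)
  # identical groups give ANOVA F = 0
  expect_equal(ts2$anova_F, 0)
  expect_error(trait_stats(c(1, 2)), "at least 3")
  # constant vector: Shapiro undefined and flagged
  tc <- trait_stats(rep(1, 10))
  expect_true(tc$constant)
  expect_true(is.na(tc$shapiro_W))
})

test_that("trait transformations behave as documented", {
  expect_equal(as.numeric(transform_trait(8, "curt")), 2)
  expect_equal(as.numeric(transform_trait(c(1, exp(1), exp(2)), "ln")),
               c(0, 1, 2))
  # negative support triggers a recorded shift for ln
  tr <- transform_trait(c(-1, 0, 3), "ln")
  expect_gt(attr(tr, "shift"), 1 - 1e-9)
  expect_error(transform_trait(c(NA, NA), "ln"), "missing")
  # the Tukey ladder picks the log for lognormal data most of the time
  hit <- vapply(1:50, function(s) {
    set.seed(s)
    x <- exp(rnorm(120, sd = 1.5))
    identical(attr(transform_trait(x, "tukey"), "lambda"), 0)
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("transmission probabilities are coherent and informative", {
  fix <- scan_fixture()
  probs <- fix$probs
  g1 <- probs$groups[[1]]
  expect_true(all(abs(rowSums(cbind(g1$pm[, 1] * g1$pp[, 1],
                                    g1$pm[, 1] * (1 - g1$pp[, 1]),
                                    (1 - g1$pm[, 1]) * g1$pp[, 1],
                                    (1 - g1$pm[, 1]) * (1 - g1$pp[, 1]))) - 1)
                  < 1e-9))
  expect_true(all(g1$pm >= 0 & g1$pm <= 1))
  # with eps = 0, a fully informative marker pins its own position
  lmx <- mk_geno(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
                 seg_type = "lmxll")
  map1 <- mk_map(list(LG1 = data.frame(
    id = c("a", "b"), cM = c(0, 20), lod_sum = 1, seg_type = "lmxll",
    chrom = "chr01", start = 1, end = 2, snp_count = 1)))
  pr <- transmission_probs(map1, lmx, step_cM = 10, eps = 0)
  at0 <- which(pr$groups$LG1$grid == 0)
  expect_equal(pr$groups$LG1$pm[at0, ], c(1, 0, 1, 0) [1:4],
               tolerance = 1e-9, ignore_attr = TRUE)
  # no paternal information: paternal chain stays at 1/2
  expect_true(all(abs(pr$groups$LG1$pp - 0.5) < 1e-12))
  # midway between concordant flanking markers 20 cM apart, the
  # two-point conditional probability holds
  r1 <- kosambi_inverse(10)
  want <- (1 - r1)^2 / ((1 - r1)^2 + r1^2)
  mid <- which(pr$groups$LG1$grid == 10)
  expect_equal(pr$groups$LG1$pm[mid, 1], want, tolerance = 1e-9)
})

test_that("interval mapping finds a deterministic QTL with full PVE", {
  fix <- scan_fixture()
  q <- list(chrom = "chr01", pos_cM = 40, effects = c(2, 1, -1, -2),
            pve = 1)
  y <- simulate_traits(fix$pop$truth, qtl_spec = list(q), seed = 4)
  scan <- interval_mapping(y, fix$probs)
  expect_gt(nrow(scan$peaks), 0)
  top <- scan$peaks[which.max(scan$peaks$lod), ]
  expect_gt(top$pve, 80)
  # the peak must sit near the bin carrying the planted marker
  mk <- fix$pop$truth$marker[fix$pop$truth$marker$id ==
                               attr(y, "qtl")[[1]]$marker, ]
  gmap <- fix$map$groups[[top$lg]]
  hit <- gmap[gmap$chrom == mk$chrom & gmap$start <= mk$pos &
                gmap$end >= mk$pos, ]
  expect_gt(nrow(hit), 0)
  expect_lt(min(abs(hit$cM - top$cM)), 10)
  # support intervals nest and contain the peak
  expect_true(all(scan$peaks$ci2_lo <= scan$peaks$ci1_lo))
  expect_true(all(scan$peaks$ci2_hi >= scan$peaks$ci1_hi))
  expect_true(all(scan$peaks$cM >= scan$peaks$ci1_lo &
                    scan$peaks$cM <= scan$peaks$ci1_hi))
})

test_that("the LOD curve is invariant to affine trait transformation", {
  fix <- scan_fixture()
  y <- simulate_traits(fix$pop$truth, h2_polygenic = 0.3, seed = 8)
  s1 <- interval_mapping(y, fix$probs)
  s2 <- interval_mapping(3.7 * as.numeric(y) - 11, fix$probs)
  expect_equal(s1$curve$lod, s2$curve$lod, tolerance = 1e-8)
})

test_that("Kruskal-Wallis scan matches hand computation and guards ties", {
  g <- mk_geno(a = c(0L, 0L, 0L, 1L, 1L, 1L), seg_type = "lmxll")
  kw <- kw_scan(c(1, 2, 3, 4, 5, 6), g, alpha = 0.005)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1L)
  # all tied values give H = 0
  kw0 <- kw_scan(rep(2, 6), g)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$P, 1)
  # a single genotype class is skipped
  g1 <- mk_geno(a = rep(0L, 6), seg_type = "lmxll")
  expect_true(is.na(kw_scan(c(1, 2, 3, 4, 5, 6), g1)$H))
})

test_that("null Kruskal-Wallis scans reject at about the nominal rate", {
  set.seed(42)
  codes <- matrix(rbinom(2000 * 176, 1, 0.5), 2000)
  args <- setNames(lapply(seq_len(50), function(i) codes[i, ]), paste0("m", 1:50))
  y <- rnorm(176)
  # vectorized check over 2000 independent null markers
  P <- vapply(seq_len(2000), function(i)
    kruskal.test(y, factor(codes[i, ]))$p.value, 0)
  expect_lt(abs(mean(P < 0.005) - 0.005), 0.004)
})

test_that("QTL stability matching uses a strict per-group 10 cM rule", {
  mk_scan <- function(df) structure(list(peaks = df), class = "qtl_scan")
  a <- mk_scan(data.frame(lg = c("LG1", "LG2"), cM = c(10, 30),
                          lod = 3, pve = 5))
  b <- mk_scan(data.frame(lg = c("LG1", "LG3"), cM = c(19.9, 30),
                          lod = 3, pve = 5))
  m <- qtl_stability(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$delta_cM, 9.9)
  # exactly 10 cM apart: not matched
  b2 <- mk_scan(data.frame(lg = "LG1", cM = 20, lod = 3, pve = 5))
  expect_equal(nrow(qtl_stability(a, b2)), 0)
  # same position matches at zero distance
  expect_equal(qtl_stability(a, a)$delta_cM, c(0, 0))
})

test_that("QTL support intervals project and merge physical spans", {
  scan <- structure(list(peaks = data.frame(
    lg = "LG1", cM = 5, lod = 4, pve = 10, ci1_lo = 0, ci1_hi = 10,
    ci2_lo = 0, ci2_hi = 12)), class = "qtl_scan")
  map <- mk_map(list(LG1 = data.frame(
    id = c("b1", "b2", "b3"), cM = c(0, 5, 11),
    seg_type = "lmxll", chrom = "chr01",
    start = c(100e3, 150e3, 400e3), end = c(200e3, 300e3, 500e3),
    snp_count = 1)))
  bins <- mk_geno(b1 = c(0L, 1L), b2 = c(0L, 1L), b3 = c(0L, 1L),
                  seg_type = "lmxll",
                  start = c(100e3, 150e3, 400e3),
                  end = c(200e3, 300e3, 500e3))
  out <- qtl_to_physical(scan, map, bins, drop = 1)
  # b1 and b2 overlap and merge; b3 lies outside the 1-LOD interval
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(100e3, 300e3))
  # empty support interval gives empty output
  scan0 <- structure(list(peaks = scan$peaks[0, ]), class = "qtl_scan")
  expect_equal(nrow(qtl_to_physical(scan0, map, bins)), 0)
  # gene annotation intersects merged intervals
  ann <- data.frame(chrom = "chr01", start = c(120e3, 390e3),
                    end = c(130e3, 410e3), gene_id = c("gA", "gB"))
  out2 <- qtl_to_physical(scan, map, bins, annotation = ann)
  expect_equal(out2$genes, "gA")
})

test_that("1-LOD physical intervals usually cover the causal position", {
  fix <- scan_fixture()
  cover <- 0; found <- 0
  for (s in 1:8) {
    y <- simulate_traits(fix$pop$truth,
                         qtl_spec = list(list(chrom = "chr02", pos_cM = 35,
                                              effects = c(1, 0, 0, -1),
                                              pve = 0.3)), seed = 20 + s)
    sc <- interval_mapping(y, fix$probs)
    if (!nrow(sc$peaks)) next
    found <- found + 1
    phys <- qtl_to_physical(sc, fix$map, fix$bins, drop = 1)
    mk <- fix$pop$truth$marker[fix$pop$truth$marker$id ==
                                 attr(y, "qtl")[[1]]$marker, ]
    hit <- any(phys$chrom == mk$chrom & phys$start <= mk$pos &
                 phys$end >= mk$pos)
    cover <- cover + hit
  }
  expect_gte(found, 6)
  expect_gte(cover / found, 0.8)
})

test_that("GRM heritability recovers the planted extremes", {
  fix <- scan_fixture()
  y1 <- simulate_traits(fix$pop$truth, h2_polygenic = 1, seed = 5)
  h1 <- suppressWarnings(heritability(fix$bins, y1))
  expect_gte(h1$h2, 0.95)
  y0 <- simulate_traits(fix$pop$truth, h2_polygenic = 0, seed = 6)
  h0 <- suppressWarnings(heritability(fix$bins, y0))
  expect_lte(h0$h2, 0.1)
  expect_equal(h0$h2, h0$sigma_g2 / (h0$sigma_g2 + h0$sigma_e2),
               tolerance = 1e-9)
  expect_error(heritability(fix$bins, rep(1, 10)), "50")
})
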