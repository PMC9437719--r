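test_that("two-point estimates match hand-computable cases", {
  g <- mk_geno(a = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L),
               b = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L),
               seg_type = "lmxll")
  est <- estimate_rf(g, "a", "b", min_joint = 4)
  expect_equal(est$r, 0.25, tolerance = 1e-6)
  expect_equal(unname(est$phase[["maternal"]]), "coupling")
  # identical vectors: r = 0, large LOD
  g2 <- mk_geno(a = rep(c(0L, 1L), 88), b = rep(c(0L, 1L), 88),
                seg_type = "lmxll")
  est2 <- estimate_rf(g2, "a", "b")
  expect_equal(est2$r, 0, tolerance = 1e-6)
  expect_gt(est2$lod, 20)
  # complementary vectors resolve to r = 0 in repulsion
  g3 <- mk_geno(a = rep(c(0L, 1L), 50), b = rep(c(1L, 0L), 50),
                seg_type = "lmxll")
  est3 <- estimate_rf(g3, "a", "b")
  expect_equal(est3$r, 0, tolerance = 1e-6)
  expect_equal(unname(est3$phase[["maternal"]]), "repulsion")
})

test_that("cross-parent pairs share no meiosis and are flagged", {
  set.seed(4)
  g <- mk_geno(a = rbinom(200, 1, 0.5), b = rbinom(200, 1, 0.5),
               seg_type = c("lmxll", "nnxnp"))
  est <- estimate_rf(g, "a", "b")
  expect_true(is.na(est$r))
  expect_false(est$usable)
  expect_lt(est$ind_lod, 2)
  # too few joint observations also flags the estimate
  g4 <- mk_geno(a = c(0L, 1L, NA, NA), b = c(0L, 1L, 0L, 1L),
                seg_type = "lmxll")
  expect_false(estimate_rf(g4, "a", "b")$usable)
})

test_that("EM recovers r without bias across type pairs and phases", {
  set.seed(12)
  n <- 4000
  for (r in c(0.05, 0.2)) {
    Sm1 <- rbinom(n, 1, 0.5); Sm2 <- (Sm1 + rbinom(n, 1, r)) %% 2L
    Sp2 <- rbinom(n, 1, 0.5)
    for (ph in 0:1) {
      hk <- bitwXor(Sm2, ph) + Sp2
      g <- mk_geno(a = Sm1, b = as.integer(hk),
                   seg_type = c("lmxll", "hkxhk"))
      est <- estimate_rf(g, "a", "b")
      expect_lt(abs(est$r - r), 0.02)
      expect_equal(unname(est$phase[["maternal"]]),
                   c("coupling", "repulsion")[ph + 1])
    }
  }
})

test_that("rf matrices are symmetric with r in [0, 0.5]", {
  pop <- small_pop(seed = 6, n = 60, n_chrom = 1, snps = 300,
                   len_bp = 3e6, cM = 40)
  flt <- filter_sites(segregation_chi2(classify_segregation(
    as_snp_data(pop))))
  bins <- bin_markers(flt$sites)
  rfm <- rf_matrix(bins, min_joint = 10)
  expect_true(isSymmetric(rfm$r, check.attributes = FALSE))
  expect_true(isSymmetric(rfm$ind_lod, check.attributes = FALSE))
  expect_true(all(rfm$r >= 0 & rfm$r <= 0.5, na.rm = TRUE))
  expect_true(all(rfm$lod >= 0, na.rm = TRUE))
})

test_that("grouping recovers chromosomes and applies the missing rule", {
  pop <- small_pop(seed = 8, n = 100, n_chrom = 2, snps = 500,
                   len_bp = 5e6, cM = 60)
  flt <- filter_sites(segregation_chi2(classify_segregation(
    as_snp_data(pop))))
  bins <- bin_markers(flt$sites)
  # plant missing calls on one marker beyond the exclusion bound
  bins$codes[3, 1:10] <- NA
  gr <- group_markers(bins, parent = "maternal", max_missing = 9)
  expect_equal(length(Filter(function(g) length(g) > 2, gr$groups)), 2)
  expect_true(bins$info$id[3] %in% gr$excluded ||
                !bins$info$id[3] %in% unlist(gr$groups))
  expect_true(all(gr$ladder$n_groups[gr$ladder$threshold > 9] >=
                    max(2, 0)))
  # a marker with exactly 9 missing calls is retained
  bins$codes[3, ] <- bins$codes[4, ]
  bins$codes[3, 1:9] <- NA
  gr2 <- group_markers(bins, parent = "maternal", max_missing = 9)
  expect_false(bins$info$id[3] %in% gr2$excluded)
  # an absurd threshold shatters the groups into singletons
  gr3 <- group_markers(bins, parent = "maternal", ind_lod_min = 1e6)
  expect_true(all(lengths(gr3$groups) == 1))
})

test_that("rf structure is block-diagonal and error inflates map length", {
  pop0 <- small_pop(seed = 51, n = 80, n_chrom = 2, snps = 400,
                    len_bp = 4e6, cM = 50)
  build_len <- function(err, seed) {
    pop <- small_pop(seed = seed, n = 80, error = err, n_chrom = 2,
                     snps = 400, len_bp = 4e6, cM = 50)
    flt <- filter_sites(segregation_chi2(classify_segregation(
      as_snp_data(pop))))
    bins <- bin_markers(flt$sites)
    maps <- build_parental_maps(bins, max_missing = 20)
    list(maps = maps, bins = bins)
  }
  clean <- build_len(0, 51)
  # within-group r is lower than between-group r (block diagonal)
  gr <- group_markers(clean$bins, parent = "maternal", max_missing = 20)
  ids <- unlist(gr$groups[lengths(gr$groups) > 2])
  member <- rep(seq_along(gr$groups[lengths(gr$groups) > 2]),
                lengths(gr$groups[lengths(gr$groups) > 2]))
  R <- gr$rf$r[ids, ids]
  same <- outer(member, member, "==")
  expect_lt(mean(R[same & upper.tri(R)], na.rm = TRUE),
            mean(R[!same & upper.tri(R)], na.rm = TRUE))
  # genotyping error does not shrink the map
  noisy <- build_len(0.05, 51)
  len_of <- function(maps) sum(vapply(maps$maternal$groups,
                                      function(g) max(g$cM), 0))
  expect_gte(len_of(noisy$maps), len_of(clean$maps) * 0.9)
})

test_that("ordering matches brute force on small noise-free groups", {
  set.seed(15)
  hits <- 0
  for (rep in 1:20) {
    pos <- sort(runif(5, 0, 60))
    D <- abs(outer(pos, pos, "-"))
    R <- kosambi_inverse(D)
    ids <- paste0("m", 1:5)
    rfm <- structure(list(
      r = structure(R, dimnames = list(ids, ids)),
      lod = structure(matrix(20, 5, 5), dimnames = list(ids, ids)),
      n_joint = matrix(176, 5, 5),
      info = data.frame(id = ids)), class = "rf_matrix")
    og <- order_group(ids, rfm, resid_drop = Inf)
    found <- match(og$id, ids)
    ok <- identical(found, 1:5) || identical(found, 5:1)
    # brute force over all 120 orders under the same fitted-gap objective
    Dc <- kosambi(pmin(R, 0.4999)); diag(Dc) <- 0
    rc <- pmin(pmax(R, 1 / 352), 0.49)
    W <- (1 - 4 * rc^2)^2 / (rc * (1 - rc)); diag(W) <- 0
    oracle <- oracle_best_order(Dc, W)
    hits <- hits + (attr(og, "objective") <= oracle$obj + 1e-6)
    expect_true(ok)
  }
  expect_gte(hits, 19)
})

test_that("two-marker groups span their two-point Kosambi distance", {
  g <- mk_geno(a = rep(c(0L, 1L), 44), b = c(rep(c(0L, 1L), 40), rep(c(1L, 0L), 4)),
               seg_type = "lmxll")
  rfm <- rf_matrix(g, min_joint = 10)
  og <- order_group(c("a", "b"), rfm)
  expect_equal(max(og$cM), kosambi(rfm$r["a", "b"]), tolerance = 1e-9)
})

test_that("parental maps use the sets that inform each parent", {
  pop <- small_pop(seed = 23, n = 90, n_chrom = 1, snps = 400,
                   len_bp = 4e6, cM = 50)
  flt <- filter_sites(segregation_chi2(classify_segregation(
    as_snp_data(pop))))
  bins <- bin_markers(flt$sites)
  # lmxll-only genotypes: paternal map must come out empty
  lm_only <- subset_geno_pub(bins, bins$info$id[bins$info$seg_type == "lmxll"])
  maps <- build_parental_maps(lm_only)
  expect_equal(length(maps$paternal$groups), 0)
  expect_gt(length(maps$maternal$groups), 0)
  # hkxhk-only: both maps built from identical marker sets
  hk_only <- subset_geno_pub(bins, bins$info$id[bins$info$seg_type == "hkxhk"])
  maps2 <- build_parental_maps(hk_only, max_missing = 30)
  expect_setequal(unname(unlist(lapply(maps2$maternal$groups, `[[`, "id"))),
                  unname(unlist(lapply(maps2$paternal$groups, `[[`, "id"))))
})

test_that("map summary reproduces the published interval arithmetic", {
  # fabricated map with the published per-group marker counts and spans
  lens <- c(68.6, 82.9, 85.6, 82.8, 81.4, 87.0, 75.0, 70.1, 82.9, 81.1,
            75.1, 70.5, 69.0, 78.1, 96.1, 91.0, 81.2)
  ns <- c(127, 190, 207, 197, 225, 81, 189, 160, 152, 279, 167, 138,
          166, 203, 258, 252, 199)
  frames <- lapply(seq_along(lens), function(k) {
    data.frame(id = paste0("g", k, "_", seq_len(ns[k])),
               cM = seq(0, lens[k], length.out = ns[k]),
               seg_type = "lmxll", chrom = sprintf("chr%02d", k),
               start = 1, end = 2, snp_count = 1)
  })
  names(frames) <- paste0("LG", seq_along(frames))
  sm <- map_summary(mk_map(frames))
  expect_equal(sm$avg_interval_cM[sm$linkage_group == "LG6"], 1.09,
               tolerance = 0.005)
  expect_equal(sm$avg_interval_cM[sm$linkage_group == "Total"], 0.43,
               tolerance = 0.005)
  expect_equal(sm$n_markers[sm$linkage_group == "Total"], 3190)
  # published total is the rounded sum of per-group lengths
  expect_equal(sm$length_cM[sm$linkage_group == "Total"], 1358.5,
               tolerance = 1e-4)
  # two markers 10 cM apart: interval is 10
  one <- mk_map(list(LG1 = data.frame(id = c("a", "b"), cM = c(0, 10),
                                      seg_type = "lmxll", chrom = "chr01",
                                      start = 1, end = 2, snp_count = 1)))
  expect_equal(map_summary(one)$avg_interval_cM[1], 10)
})

test_that("consensus merging aligns bridges and projects the rest", {
  mkf <- function(ids, cM) data.frame(id = ids, cM = cM, lod_sum = 10,
                                      seg_type = "hkxhk", chrom = "chr01",
                                      start = 1, end = 2, snp_count = 1)
  # identical parental groups: consensus equals input
  m <- mk_map(list(LG1 = mkf(c("h1", "h2", "h3"), c(0, 25, 50))), "maternal")
  p <- mk_map(list(LG1 = mkf(c("h1", "h2", "h3"), c(0, 25, 50))), "paternal")
  cons <- merge_consensus(m, p)
  expect_equal(cons$groups[[1]]$cM, c(0, 25, 50))
  expect_equal(nrow(cons$groups[[1]]), 3)
  # bridges at (0,0) and (50,60); maternal-only marker at 25 -> 30
  m2 <- mk_map(list(LG1 = mkf(c("h1", "a", "h2"), c(0, 25, 50))), "maternal")
  p2 <- mk_map(list(LG1 = mkf(c("h1", "h2"), c(0, 60))), "paternal")
  cons2 <- merge_consensus(m2, p2)
  g <- cons2$groups[[1]]
  expect_equal(g$cM[g$id == "a"], 30)
  expect_equal(g$cM[g$id == "h2"], 60)
  # every parental marker appears exactly once
  expect_setequal(g$id, c("h1", "a", "h2"))
})

test_that("consensus falls back to joint re-grouping without bridges", {
  pop <- small_pop(seed = 31, n = 100, n_chrom = 1, snps = 500,
                   len_bp = 5e6, cM = 50)
  flt <- filter_sites(segregation_chi2(classify_segregation(
    as_snp_data(pop))))
  bins <- bin_markers(flt$sites)
  maps <- build_parental_maps(bins)
  mat <- maps$maternal; pat <- maps$paternal
  # strip the bridge markers from the maternal group to force the fallback
  mat$groups <- lapply(mat$groups, function(g) g[g$seg_type == "lmxll", ])
  cons <- suppressWarnings(merge_consensus(mat, pat, bins = bins))
  ids <- unlist(lapply(cons$groups, `[[`, "id"))
  expect_true(all(unlist(lapply(mat$groups, `[[`, "id")) %in% ids))
  expect_false(any(duplicated(ids)))
})
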