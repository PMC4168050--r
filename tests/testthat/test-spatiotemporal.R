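test_that("temporal ratios divide replicate-averaged signals by the reference dpi", {
  means <- rbind(gA = c(9, 9, 5000, 8000, 10000, 10000),
                 gB = rep(400, 6),
                 gC = c(0, 0, 0, 0, 0, 0))
  dpi <- c(0, 3, 4, 6, 10, 14)
  cmp <- toy_timecourse(means, dpi)
  tr <- temporal_ratios(cmp, timepoints = dpi, reference = 14)
  expect_equal(tr$ratios["gA", "4"], 0.5)
  expect_equal(tr$ratios["gB", ], stats::setNames(rep(1, 6),
                                                  as.character(dpi)))
  expect_false(tr$defined[["gC"]])
  expect_true(all(is.na(tr$ratios["gC", ])))
  expect_equal(tr$ratios[, "14"][tr$defined], c(gA = 1, gB = 1))
  # descending ratio ordering per timepoint (gB's flat ratio 1 > gA's 0.5)
  expect_identical(tr$ordering[["4"]][1:2], c("gB", "gA"))

  expect_error(temporal_ratios(cmp, timepoints = c(4, 6, 99),
                               reference = 14), "99")
})

test_that("planted late waves lag early waves in 4 dpi activation ratios", {
  tg <- SIM$truth$genes
  tr <- temporal_ratios(SIM$compendium, genes = FAM)
  r4 <- tr$ratios[, "4"]
  w <- tg$wave[match(rownames(tr$ratios), tg$gene_id)]
  expect_lt(stats::median(r4[w == 3]), stats::median(r4[w == 1]))
  expect_lt(stats::median(r4[w == 2]), stats::median(r4[w == 1]))
})

test_that("timepoint correlation handles exact, degenerate and planted cases", {
  means <- rbind(gA = c(1, 1, 2, 5), gB = c(4, 4, 8, 2),
                 gC = c(10, 10, 20, 7))
  cmp <- toy_timecourse(means, c(0, 3, 4, 6))
  r <- timepoint_correlation(cmp, timepoints = c(0, 3, 4, 6),
                             genes = rownames(means))
  expect_equal(r["0", "3"], 1)          # identical vectors
  expect_equal(r["0", "4"], 1)          # proportional vectors
  expect_true(isSymmetric(r))
  expect_equal(diag(r), stats::setNames(rep(1, 4), colnames(r)))

  neg <- toy_timecourse(rbind(gA = c(1, 3), gB = c(2, 2), gC = c(3, 1)),
                        c(0, 3))
  rn <- timepoint_correlation(neg, timepoints = c(0, 3),
                              genes = c("gA", "gB", "gC"))
  expect_equal(rn["0", "3"], -1)

  flat <- toy_timecourse(rbind(gA = c(5, 1), gB = c(5, 2), gC = c(5, 7)),
                         c(0, 3))
  rf <- timepoint_correlation(flat, timepoints = c(0, 3),
                              genes = c("gA", "gB", "gC"))
  expect_true(is.na(rf["0", "3"]))      # zero-variance vector at 0 dpi

  # family profiles: quiescent and fully activated phases each cohere
  rs <- timepoint_correlation(SIM$compendium, genes = FAM)
  expect_gt(rs["0", "3"], 0.99)
  expect_gt(rs["10", "14"], 0.95)
  expect_gt(rs["10", "14"], rs["4", "14"])
  ev <- eigen(rs, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))          # positive semidefinite
})

test_that("zone profiles are log2 ratios to the five-zone mean", {
  zones <- c("zone_I", "zone_II", "zone_II_III", "zone_III", "zone_IV")
  sig <- rbind(flat = rep(10, 5), apex = c(16, 8, 4, 2, 2),
               dbl = c(10, 5, 5, 3, 2))
  colnames(sig) <- paste0(zones, "_1")
  cmp <- compendium(sig, toy_meta(colnames(sig), organ = "nodule",
                                  cls = zones))
  zp <- zone_relative_profile(cmp)
  expect_equal(zp$profile["flat", ],
               stats::setNames(rep(0, 5), zones))
  expect_equal(zp$profile["apex", "zone_I"], log2(16 / 6.4))
  expect_equal(zp$profile["dbl", "zone_I"], 1)   # exactly 2x the mean
  # back-transform invariant: mean of 2^profile is 1
  expect_equal(rowMeans(2^zp$profile), c(flat = 1, apex = 1, dbl = 1),
               tolerance = 1e-9)

  sig2 <- sig[, -1, drop = FALSE]
  cmp2 <- compendium(sig2, toy_meta(colnames(sig2), organ = "nodule",
                                    cls = zones[-1]))
  expect_error(zone_relative_profile(cmp2), "zone_I")
})

test_that("zone back-transform holds on synthetic family profiles", {
  zp <- zone_relative_profile(SIM$compendium, genes = FAM)
  expect_true(all(zp$defined))
  expect_equal(unname(rowMeans(2^zp$profile)), rep(1, length(FAM)),
               tolerance = 1e-9)
  # early waves peak apically, late waves proximally
  tg <- SIM$truth$genes
  w <- tg$wave[match(rownames(zp$profile), tg$gene_id)]
  peak_zone <- apply(zp$profile, 1L, which.max)
  expect_lt(stats::median(peak_zone[w == 1]),
            stats::median(peak_zone[w == 3]))
})

test_that("wave assignment follows the activation rule and its monotonicity", {
  means <- rbind(full = c(9, 9, 1000, 1000, 1000, 1000, 1000),
                 late = c(9, 9, 9, 9, 900, 1000, 1000),
                 silent = rep(9, 7),
                 fading = c(9, 9, 800, 800, 800, 800, 100))
  dpi <- c(0, 3, 4, 6, 10, 14, 28)
  cmp <- toy_timecourse(means, dpi)
  tr <- temporal_ratios(cmp, timepoints = dpi)
  wt <- assign_waves(tr, cmp, background = 9)
  w <- stats::setNames(wt$wave, wt$gene_id)
  expect_identical(w[["full"]], "1")
  expect_identical(w[["late"]], "3")
  expect_identical(w[["silent"]], "unassigned")
  m <- stats::setNames(wt$maintenance, wt$gene_id)
  expect_identical(m[["full"]], "maintained")
  expect_identical(m[["fading"]], "declining")

  # raising the activation threshold can only delay waves
  tr_s <- temporal_ratios(SIM$compendium, genes = FAM)
  lvl <- c("1" = 1, "2" = 2, "3" = 3, unassigned = 4)
  prev <- NULL
  for (f in c(0.3, 0.5, 0.7)) {
    cur <- lvl[assign_waves(tr_s, SIM$compendium,
                            activation_fraction = f)$wave]
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("planted wave labels are recovered", {
  tg <- SIM$truth$genes
  tr <- temporal_ratios(SIM$compendium, genes = FAM)
  wt <- assign_waves(tr, SIM$compendium)
  acc <- mean(wt$wave == as.character(tg$wave[match(wt$gene_id,
                                                    tg$gene_id)]))
  expect_gte(acc, 0.9)
  # planted declining genes are classified as declining
  decl <- tg$declining[match(wt$gene_id, tg$gene_id)]
  expect_gt(mean((wt$maintenance == "declining") == decl), 0.9)
})

test_that("UPGMA reproduces hand-computable merges and breaks ties deterministically", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  d <- hierarchical_cluster(m)
  expect_equal(d$height, c(1, 1, 10))
  expect_identical(d$labels[d$order], c("a", "b", "c", "d"))

  # two identical rows among three merge first at height zero
  m2 <- rbind(x = c(1, 2), y = c(5, 9), z = c(1, 2))
  d2 <- hierarchical_cluster(m2)
  expect_equal(d2$height[1], 0)
  expect_identical(sort(d2$labels[-d2$merge[1, ]]), c("x", "z"))

  # permutation of rows: same topology (heights) and leaf multiset
  set.seed(21)
  m3 <- matrix(stats::rnorm(24), 6, 4,
               dimnames = list(letters[1:6], NULL))
  d3 <- hierarchical_cluster(m3)
  perm <- sample.int(6)
  d3p <- hierarchical_cluster(m3[perm, , drop = FALSE])
  expect_equal(d3$height, d3p$height, tolerance = 1e-12)
  expect_setequal(d3$labels[d3$order], d3p$labels[d3p$order])
})

test_that("UPGMA merge heights match brute-force average linkage and hclust", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm(24), 6, 4,
                dimnames = list(paste0("g", 1:6), NULL))
    d <- hierarchical_cluster(m)
    expect_equal(d$height, oracle_upgma_heights(m), tolerance = 1e-9)
    hc <- stats::hclust(stats::dist(m), method = "average")
    expect_equal(d$height, hc$height, tolerance = 1e-9)
  }
  # pearson distance agrees with the oracle too, and rejects flat rows
  m <- matrix(stats::rlnorm(24), 6, 4, dimnames = list(paste0("g", 1:6),
                                                       NULL))
  d <- hierarchical_cluster(m, distance = "pearson")
  expect_equal(d$height, oracle_upgma_heights(m, "pearson"),
               tolerance = 1e-9)
  m[2, ] <- 7
  expect_error(hierarchical_cluster(m, distance = "pearson"), "g2")
})

test_that("heat-map scaling modes are exact and consistent with zone profiles", {
  m <- rbind(a = c(0, 5, 10), b = c(0, 0, 0))
  expect_equal(heatmap_matrix(m, "none"),
               structure(m, flagged_rows = character(0)))
  rm_ <- heatmap_matrix(m, "row_max")
  expect_equal(rm_["a", ], c(0, 0.5, 1))
  expect_equal(rm_["b", ], c(0, 0, 0))
  expect_identical(attr(rm_, "flagged_rows"), "b")

  zp <- zone_relative_profile(SIM$compendium, genes = FAM[1:10])
  lg <- heatmap_matrix(zp$zone_means, "log2_ratio")
  expect_equal(lg[, ], zp$profile, tolerance = 1e-12)
})
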