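screen_toy <- function(values_A, values_B, gene = "g1") {
  nA <- length(values_A); nB <- length(values_B)
  ids <- c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB)))
  sig <- matrix(c(values_A, values_B), nrow = 1,
                dimnames = list(gene, ids))
  cmp <- compendium(sig, toy_meta(ids, organ = "nodule"))
  list(cmp = cmp, A = sprintf("A%d", seq_len(nA)),
       B = sprintf("B%d", seq_len(nB)))
}

test_that("the Welch screen matches the closed-form t-test", {
  a <- c(120.5, 98.2, 143.9)
  b <- c(310.4, 271.8, 355.0)
  tc <- screen_toy(a, b)
  for (alt in c("B_greater", "two_sided")) {
    res <- two_group_screen(tc$cmp, tc$A, tc$B, alternative = alt)
    expect_equal(res$p_value, oracle_welch_p(a, b, alt), tolerance = 1e-9)
    expect_equal(res$p_value,
                 stats::t.test(b, a, var.equal = FALSE,
                               alternative = if (alt == "B_greater")
                                 "greater" else "two.sided")$p.value,
                 tolerance = 1e-12)
  }
  res <- two_group_screen(tc$cmp, tc$A, tc$B)
  expect_equal(res$fold_change, mean(b) / mean(a))
  expect_identical(res$direction, "higher_in_B")
  expect_true(res$flagged)
})

test_that("degenerate and invalid screen inputs behave as specified", {
  tc <- screen_toy(c(5, 5, 5), c(5, 5, 5))
  res <- two_group_screen(tc$cmp, tc$A, tc$B)
  expect_equal(res$p_value, 1)          # zero variance, equal means
  expect_equal(res$fold_change, 1)
  expect_false(res$flagged)
  expect_identical(res$direction, "none")

  expect_error(two_group_screen(tc$cmp, tc$A[1], tc$B),
               "at least 2 replicate")
  expect_error(two_group_screen(tc$cmp, c(tc$A, "nope"), tc$B), "nope")
})

test_that("screen flags are invariant to condition order and BH mode only adds q-values", {
  grp <- function(cls) SIM$compendium$conditions$condition_id[
    SIM$compendium$conditions$sample_class == cls]
  r1 <- two_group_screen(SIM$compendium, grp("lcm_IC"), grp("lcm_UC"),
                         genes = FAM)
  r2 <- two_group_screen(SIM$compendium, rev(grp("lcm_IC")),
                         rev(grp("lcm_UC")), genes = FAM)
  expect_identical(r1$flagged, r2$flagged)
  expect_equal(r1$p_value, r2$p_value)

  rb <- two_group_screen(SIM$compendium, grp("lcm_IC"), grp("lcm_UC"),
                         genes = FAM, bh = TRUE)
  expect_identical(rb$flagged, r1$flagged)
  expect_true(all(rb$q_value >= rb$p_value - 1e-15))
})

test_that("the planted UC-excess gene is the top hit of the infected/uninfected screen", {
  grp <- function(cls) SIM$compendium$conditions$condition_id[
    SIM$compendium$conditions$sample_class == cls]
  res <- two_group_screen(SIM$compendium, grp("lcm_IC"), grp("lcm_UC"),
                          genes = FAM, alternative = "B_greater")
  tg <- SIM$truth$genes
  planted <- tg$gene_id[!is.na(tg$uc_fold)]
  top_fold <- tg$gene_id[which.max(tg$uc_fold)]
  expect_true(all(res$flagged[match(planted, res$gene_id)]))
  expect_identical(res$gene_id[which.max(res$fold_change)], top_fold)
  expect_identical(res$gene_id[which.min(res$p_value)], top_fold)
  # fold of the strongest planted excess recovered within noise
  f <- res$fold_change[match(top_fold, res$gene_id)]
  expect_lt(abs(log2(f / max(tg$uc_fold, na.rm = TRUE))), log2(1.35))
  # no other family gene reaches significance
  expect_equal(sum(res$flagged), length(planted))
})

test_that("no family gene is higher expressed in the senescent zone IV", {
  grp <- function(cls) SIM$compendium$conditions$condition_id[
    SIM$compendium$conditions$sample_class == cls]
  res <- two_group_screen(SIM$compendium, grp("zone_III"), grp("zone_IV"),
                          genes = FAM, alternative = "B_greater")
  expect_equal(sum(res$flagged), 0L)
})

test_that("senescence induction shuts the family down and lights the markers up", {
  m <- SIM$compendium$conditions
  ctl <- m$condition_id[m$treatment == "senescence_control"]
  trt <- m$condition_id[m$treatment %in% c("nitrate", "phosphinothricin")]
  sr <- senescence_response(SIM$compendium, ctl, trt, SIM$annotation)
  pf <- sr$per_family
  expect_equal(pf$frac_down[pf$family == "NCR"], 1)
  expect_equal(pf$frac_up[pf$family == "NCR"], 0)
  expect_equal(pf$frac_up[pf$family == "senescence_marker"], 1)

  # control against itself: every ratio is exactly 1
  same <- senescence_response(SIM$compendium, ctl, ctl, SIM$annotation)
  expect_true(all(same$per_gene$ratio == 1))
  expect_true(all(same$per_family$frac_down == 0))
  expect_true(all(same$per_family$frac_up == 0))
})

test_that("expression-strength statistics are exact and structurally sound", {
  mx <- c(6000, 400, 16000, 9000)
  sig <- cbind(c1 = mx, c2 = mx / 2)
  rownames(sig) <- paste0("g", 1:4)
  cmp <- compendium(sig, toy_meta(c("c1", "c2"), organ = "leaf"))
  st <- max_signal_stats(cmp)
  expect_equal(unname(st$fractions["5000"]), 0.75)
  expect_equal(st$median, 7500)
  expect_equal(st$mean, 7850)
  expect_true(all(diff(st$fractions) <= 0))

  one <- max_signal_stats(cmp, genes = "g1")
  expect_equal(one$mean, 6000)
  expect_equal(one$median, 6000)

  # duplicating the cohort leaves fractions unchanged
  sig2 <- rbind(sig, sig)
  rownames(sig2) <- paste0("g", 1:8)
  st2 <- max_signal_stats(compendium(sig2, toy_meta(c("c1", "c2"),
                                                    organ = "leaf")))
  expect_equal(st2$fractions, st$fractions)
})

test_that("exactly the planted relaxed genes are flagged, honoring QC exclusions", {
  qc <- detect_contamination(SIM$compendium, SIM$annotation)
  contaminated <- qc$condition_id[qc$flagged]
  rf <- flag_relaxed_specificity(SIM$compendium, SIM$annotation,
                                 exclude_conditions = contaminated)
  tg <- SIM$truth$genes
  expect_setequal(rf$gene_id[rf$relaxed], tg$gene_id[tg$relaxed])

  # without the exclusion, the contaminated sample's nodule signal
  # masquerades as relaxed specificity for strictly specific genes
  rf0 <- flag_relaxed_specificity(SIM$compendium, SIM$annotation)
  gained <- setdiff(rf0$gene_id[rf0$relaxed], rf$gene_id[rf$relaxed])
  expect_gt(length(gained), 0L)
  expect_true(all(grepl("mycorrhiza", rf0$offending_conditions[
    match(gained, rf0$gene_id)])))
})

test_that("contamination QC flags only planted mixtures, monotonically in z_cut", {
  qc <- detect_contamination(SIM$compendium, SIM$annotation)
  truth_c <- SIM$truth$conditions$condition_id[
    SIM$truth$conditions$contaminated]
  expect_identical(qc$condition_id[qc$flagged], truth_c)

  loose <- detect_contamination(SIM$compendium, SIM$annotation, z_cut = 2)
  strict <- detect_contamination(SIM$compendium, SIM$annotation,
                                 z_cut = 50)
  expect_true(all(strict$condition_id[strict$flagged] %in%
                    loose$condition_id[loose$flagged]))

  expect_error(detect_contamination(SIM$compendium, SIM$annotation,
                                    marker_family = "NCR",
                                    expected_organ = "nodule"),
               NA)
  bad_ann <- SIM$annotation
  bad_ann$family[bad_ann$family == "bacterial_marker"] <- "other"
  expect_error(detect_contamination(SIM$compendium, bad_ann),
               "no marker genes")
})

test_that("clean samples are never falsely flagged across seeds", {
  false_flags <- 0L
  for (s in 1:20) {
    sim <- simulate_compendium(synthetic_config(n_genes = 150L,
                                                n_family = 20L,
                                                n_extra_conditions = 30L,
                                                seed = 1000L + s))
    qc <- detect_contamination(sim$compendium, sim$annotation)
    truth_c <- sim$truth$conditions$condition_id[
      sim$truth$conditions$contaminated]
    false_flags <- false_flags +
      sum(!qc$condition_id[qc$flagged] %in% truth_c)
  }
  expect_equal(false_flags, 0L)
})
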