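# Shared fixtures and independent oracles.

# one default synthetic compendium reused across test files
SIM <- simulate_compendium(synthetic_config())
FAM <- SIM$truth$genes$gene_id[SIM$truth$genes$is_family]

# quick condition metadata builder for hand-made compendia
toy_meta <- function(ids, organ = "nodule", treatment = "none",
                     timepoint = NA_real_, unit = NA_character_,
                     cls = "whole_organ", group = ids) {
  data.frame(condition_id = ids, organ = organ, treatment = treatment,
             timepoint = timepoint, timepoint_unit = unit,
             sample_class = cls, replicate_group = group,
             stringsAsFactors = FALSE)
}

# noise-free nodule time course: one condition per dpi per replicate,
# gene means given as a gene x dpi matrix
toy_timecourse <- function(means, dpi, reps = 2L) {
  ids <- as.vector(outer(sprintf("d%g", dpi), seq_len(reps),
                         function(d, r) sprintf("%s_r%d", d, r)))
  sig <- means[, rep(seq_along(dpi), times = reps), drop = FALSE]
  colnames(sig) <- ids
  meta <- toy_meta(ids, organ = ifelse(rep(dpi, times = reps) == 0,
                                       "root", "nodule"),
                   timepoint = rep(dpi, times = reps), unit = "dpi",
                   group = rep(sprintf("d%g", dpi), times = reps))
  compendium(sig, meta)
}

# term-by-term Shannon entropy, deliberately naive
oracle_entropy <- function(p) {
  s <- 0
  for (x in p) if (!is.na(x) && x > 0) s <- s - x * log2(x)
  s
}

# average-linkage merge heights recomputed from the original distance
# matrix at every step (no Lance-Williams update)
oracle_upgma_heights <- function(mat, distance = "euclidean") {
  n <- nrow(mat)
  D0 <- if (distance == "euclidean") as.matrix(stats::dist(mat))
        else 1 - stats::cor(t(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- mean(D0[clusters[[j]], clusters[[i]]])
        if (d < best) { best <- d; bi <- j; bj <- i }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# closed-form Welch t-test p-value
oracle_welch_p <- function(a, b, alternative = "B_greater") {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  if (alternative == "B_greater") stats::pt(t, df, lower.tail = FALSE)
  else 2 * stats::pt(-abs(t), df)
}
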