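#' Two-group differential screen (Welch t-test)
#'
#' Per gene, a Welch unequal-variance t-test on linear signals between
#' two replicate condition sets, with the fold change of group means.
#' The default replicates the original analysis: raw (uncorrected)
#' p < alpha in the stated direction flags a gene. Because family-wide
#' screens at raw alpha are anticonservative, `bh = TRUE` additionally
#' reports Benjamini-Hochberg q-values (flags stay on raw p unless
#' `flag_on = "q"`).
#'
#' @param x A [compendium()].
#' @param group_A,group_B Character vectors of condition ids, each with
#'   at least 2 replicates.
#' @param genes Optional gene subset (default all genes).
#' @param alternative `"B_greater"` (one-sided, tests mean_B > mean_A)
#'   or `"two_sided"`.
#' @param alpha Significance level (default 0.05, uncorrected).
#' @param bh Also compute Benjamini-Hochberg q-values.
#' @param flag_on `"p"` (default) or `"q"`.
#' @return Data frame of class `screen_result`: `gene_id`, `mean_A`,
#'   `mean_B`, `fold_change` (B/A), `p_value`, optional `q_value`,
#'   `direction` (`higher_in_A`/`higher_in_B`/`none`), `flagged`.
#'   When both groups have zero variance and equal means, p = 1 by
#'   convention.
#' @export
two_group_screen <- function(x, group_A, group_B, genes = NULL,
                             alternative = c("B_greater", "two_sided"),
                             alpha = 0.05, bh = FALSE,
                             flag_on = c("p", "q")) {
  stopifnot(inherits(x, "compendium"))
  alternative <- match.arg(alternative)
  flag_on <- match.arg(flag_on)
  for (g in list(group_A, group_B)) {
    unknown <- setdiff(g, colnames(x$signals))
    if (length(unknown))
      stop("unknown condition_id: ", unknown[1L], call. = FALSE)
  }
  if (length(group_A) < 2L || length(group_B) < 2L)
    stop("each group needs at least 2 replicate conditions", call. = FALSE)
  sig <- x$signals
  if (!is.null(genes)) sig <- sig[genes, , drop = FALSE]
  A <- sig[, group_A, drop = FALSE]
  B <- sig[, group_B, drop = FALSE]
  mean_A <- rowMeans(A); mean_B <- rowMeans(B)

  p <- vapply(seq_len(nrow(sig)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(1)
      # degenerate but unambiguous separation
      ok <- if (alternative == "B_greater") mean(b) > mean(a) else TRUE
      return(if (ok) 0 else 1)
    }
    alt <- if (alternative == "B_greater") "greater" else "two.sided"
    stats::t.test(b, a, alternative = alt, var.equal = FALSE)$p.value
  }, numeric(1L))

  fold <- ifelse(mean_A > 0, mean_B / mean_A,
                 ifelse(mean_B > 0, Inf, NaN))
  direction <- ifelse(mean_B > mean_A, "higher_in_B",
                      ifelse(mean_A > mean_B, "higher_in_A", "none"))
  res <- data.frame(gene_id = rownames(sig), mean_A = mean_A,
                    mean_B = mean_B, fold_change = fold, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (bh) res$q_value <- stats::p.adjust(p, method = "BH")
  res$direction <- direction
  crit <- if (flag_on == "q") {
    if (!bh) stop("flag_on = 'q' requires bh = TRUE", call. = FALSE)
    res$q_value
  } else res$p_value
  dir_ok <- if (alternative == "B_greater") direction == "higher_in_B"
  else direction != "none"
  res$flagged <- crit < alpha & dir_ok
  structure(res, class = c("screen_result", "data.frame"),
            alternative = alternative, alpha = alpha)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d genes, %d flagged (%s, alpha = %g)\n",
              nrow(x), sum(x$flagged), attr(x, "alternative"),
              attr(x, "alpha")))
  hits <- as.data.frame(x)[x$flagged, , drop = FALSE]
  if (nrow(hits))
    print.data.frame(utils::head(hits[order(hits$p_value), ], 10L))
  invisible(x)
}

#' Senescence-induction response by gene family
#'
#' Per gene the ratio of mean treated to mean control signal; per
#' family the fraction of (defined) genes with ratio below and above 1.
#' On nodules pushed into senescence the nodule-specific family shuts
#' down (all ratios < 1) while the senescence markers activate
#' strongly: the per-gene table reproduces the geometry of a
#' control-versus-treated scatter around the unit line.
#'
#' @param x A [compendium()].
#' @param control,treated Condition id sets.
#' @param annotation Gene annotation data frame (`gene_id`, `family`).
#' @return List of class `senescence_response`: `per_gene` (`gene_id`,
#'   `family`, `mean_control`, `mean_treated`, `ratio`) and
#'   `per_family` (`family`, `n`, `n_defined`, `frac_down`, `frac_up`).
#'   Genes with zero control mean have `NA` ratio and are excluded from
#'   the fractions.
#' @export
senescence_response <- function(x, control, treated, annotation) {
  stopifnot(inherits(x, "compendium"))
  for (g in list(control, treated)) {
    unknown <- setdiff(g, colnames(x$signals))
    if (length(unknown))
      stop("unknown condition_id: ", unknown[1L], call. = FALSE)
  }
  sig <- x$signals
  mc <- rowMeans(sig[, control, drop = FALSE])
  mt <- rowMeans(sig[, treated, drop = FALSE])
  ratio <- ifelse(mc > 0, mt / mc, NA_real_)
  fam <- annotation$family[match(rownames(sig), annotation$gene_id)]
  fam[is.na(fam)] <- "other"
  per_gene <- data.frame(gene_id = rownames(sig), family = fam,
                         mean_control = mc, mean_treated = mt,
                         ratio = ratio, stringsAsFactors = FALSE,
                         row.names = NULL)
  per_family <- do.call(rbind, lapply(split(per_gene, per_gene$family),
    function(d) {
      ok <- !is.na(d$ratio)
      data.frame(family = d$family[1L], n = nrow(d), n_defined = sum(ok),
                 frac_down = if (any(ok)) mean(d$ratio[ok] < 1) else NA_real_,
                 frac_up = if (any(ok)) mean(d$ratio[ok] > 1) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_family) <- NULL
  structure(list(per_gene = per_gene, per_family = per_family),
            class = "senescence_response")
}

#' @export
print.senescence_response <- function(x, ...) {
  cat("senescence_response (treated / control ratios)\n")
  print.data.frame(x$per_family)
  invisible(x)
}

#' Expression-strength statistics on per-gene maximal signals
#'
#' For every gene the maximal signal over all conditions, with the
#' cohort mean and median and the fractions of genes whose maximum
#' exceeds a set of thresholds. Comparing a gene family's statistics
#' against the whole compendium quantifies how strongly the family is
#' expressed when active.
#'
#' @param x A [compendium()].
#' @param genes Optional gene subset (default all genes).
#' @param thresholds Signal thresholds (default 5,000 / 10,000 /
#'   15,000).
#' @return List of class `max_signal_stats`: `per_gene` (named vector
#'   of maxima), `mean`, `median`, `fractions` (named by threshold).
#' @export
max_signal_stats <- function(x, genes = NULL,
                             thresholds = c(5000, 10000, 15000)) {
  stopifnot(inherits(x, "compendium"))
  sig <- x$signals
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(sig))
    if (length(unknown))
      stop("unknown gene_id: ", unknown[1L], call. = FALSE)
    sig <- sig[genes, , drop = FALSE]
  }
  if (!nrow(sig)) stop("empty gene subset", call. = FALSE)
  mx <- apply(sig, 1L, max)
  fr <- vapply(thresholds, function(th) mean(mx > th), numeric(1L))
  names(fr) <- format(thresholds, scientific = FALSE, trim = TRUE)
  structure(list(per_gene = mx, mean = mean(mx),
                 median = stats::median(mx), fractions = fr),
            class = "max_signal_stats")
}

#' @export
print.max_signal_stats <- function(x, ...) {
  cat(sprintf("max_signal_stats over %d genes: mean %.0f, median %.0f\n",
              length(x$per_gene), x$mean, x$median))
  for (nm in names(x$fractions))
    cat(sprintf("  fraction with max > %s: %.3f\n", nm, x$fractions[nm]))
  invisible(x)
}

#' Flag family genes with relaxed tissue specificity
#'
#' A family gene is relaxed when, in at least one non-target condition
#' (contamination-flagged conditions excluded), its signal exceeds
#' `max(floor_factor * background, ratio_cut * its own target-organ
#' maximum)`. The background is estimated robustly as the median
#' non-target signal of non-family genes. The default `ratio_cut` of
#' 0.01 captures exceptions expressed 10- to 100-fold lower outside the
#' target organ than in it.
#'
#' @param x A [compendium()].
#' @param annotation Annotation data frame (`gene_id`, `family`).
#' @param family Family name to screen (default `"NCR"`).
#' @param target_organ Organ the family is specific to (default
#'   `"nodule"`).
#' @param floor_factor Multiple of background (default 5).
#' @param ratio_cut Fraction of the gene's own target maximum
#'   (default 0.01).
#' @param exclude_conditions Condition ids to ignore (typically the
#'   contamination flags from [detect_contamination()]).
#' @return Data frame of class `relaxed_flags`: `gene_id`, `relaxed`,
#'   `n_offending`, `offending_conditions` (comma-separated, worst
#'   first), `max_nontarget_signal`, `threshold`. Attribute
#'   `background` stores the estimate.
#' @export
flag_relaxed_specificity <- function(x, annotation, family = "NCR",
                                     target_organ = "nodule",
                                     floor_factor = 5, ratio_cut = 0.01,
                                     exclude_conditions = character(0)) {
  stopifnot(inherits(x, "compendium"))
  fam_genes <- annotation$gene_id[annotation$family == family]
  fam_genes <- intersect(fam_genes, rownames(x$signals))
  if (!length(fam_genes))
    stop("no genes of family '", family, "' in the compendium",
         call. = FALSE)
  m <- x$conditions
  target_cols <- m$condition_id[m$organ == target_organ]
  nontarget_cols <- setdiff(m$condition_id[m$organ != target_organ],
                            exclude_conditions)
  if (!length(target_cols) || !length(nontarget_cols))
    stop("need both target and non-target conditions", call. = FALSE)

  nonfam <- setdiff(rownames(x$signals), annotation$gene_id[
    annotation$family == family])
  background <- stats::median(x$signals[nonfam, nontarget_cols])

  res <- do.call(rbind, lapply(fam_genes, function(g) {
    tgt_max <- max(x$signals[g, target_cols])
    thr <- max(floor_factor * background, ratio_cut * tgt_max)
    v <- x$signals[g, nontarget_cols]
    off <- nontarget_cols[v > thr]
    off <- off[order(-v[v > thr])]
    data.frame(gene_id = g, relaxed = length(off) > 0L,
               n_offending = length(off),
               offending_conditions = paste(off, collapse = ","),
               max_nontarget_signal = max(v), threshold = thr,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  structure(res, class = c("relaxed_flags", "data.frame"),
            background = background)
}

#' Marker-based sample contamination QC
#'
#' Screens every condition outside the expected organ for signal of a
#' marker gene set that should only be present in that organ (for
#' nodules, bacterial marker genes tracking rhizobial RNA). A condition
#' is flagged when its mean marker signal exceeds the robust background
#' `median + z_cut * MAD` computed over all non-target conditions.
#' Raising `z_cut` can only shrink the flag set.
#'
#' @param x A [compendium()].
#' @param annotation Annotation data frame.
#' @param marker_family Family whose genes are the markers (default
#'   `"bacterial_marker"`).
#' @param expected_organ Organ where marker signal is legitimate
#'   (default `"nodule"`).
#' @param z_cut Robustness multiplier (default 5).
#' @return Data frame of class `qc_report`: `condition_id`, `organ`,
#'   `marker_mean`, `flagged`, ordered by decreasing marker mean.
#'   Attributes `background_median`, `background_mad`, `threshold`.
#' @export
detect_contamination <- function(x, annotation,
                                 marker_family = "bacterial_marker",
                                 expected_organ = "nodule", z_cut = 5) {
  stopifnot(inherits(x, "compendium"))
  markers <- intersect(annotation$gene_id[annotation$family == marker_family],
                       rownames(x$signals))
  if (!length(markers))
    stop("no marker genes of family '", marker_family, "'", call. = FALSE)
  m <- x$conditions
  nt <- m$condition_id[m$organ != expected_organ]
  if (length(nt) < 3L)
    stop("need at least 3 non-target conditions to estimate background",
         call. = FALSE)
  mm <- colMeans(x$signals[markers, nt, drop = FALSE])
  med <- stats::median(mm)
  mad <- stats::mad(mm)
  thr <- med + z_cut * mad
  res <- data.frame(condition_id = nt,
                    organ = m$organ[match(nt, m$condition_id)],
                    marker_mean = mm, flagged = mm > thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$marker_mean), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("qc_report", "data.frame"),
            background_median = med, background_mad = mad, threshold = thr)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d non-target conditions, %d flagged (threshold %.2f)\n",
              nrow(x), sum(x$flagged), attr(x, "threshold")))
  if (any(x$flagged))
    print.data.frame(as.data.frame(x)[x$flagged, , drop = FALSE])
  invisible(x)
}
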