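#' Estimate the background signal level of a compendium
#'
#' A robust floor estimate used by the wave-activation rule: the 2nd
#' percentile of all signals, which on atlas-like data sits at the
#' hybridization background (around 9 on the linear scale).
#'
#' @param x A [compendium()].
#' @return A single number.
#' @export
estimate_background <- function(x) {
  stopifnot(inherits(x, "compendium"))
  as.numeric(stats::quantile(x$signals, 0.02, names = FALSE))
}

# untreated whole-organ dpi conditions (the nodule time course plus its
# 0 dpi root control)
timecourse_conditions <- function(x, timepoints) {
  m <- x$conditions
  sel <- m$sample_class == "whole_organ" & m$treatment == "none" &
    !is.na(m$timepoint) & !is.na(m$timepoint_unit) &
    m$timepoint_unit == "dpi" & m$timepoint %in% timepoints
  split(m$condition_id[sel], m$timepoint[sel])
}

# replicate-averaged gene x timepoint means over the time course
timecourse_means <- function(x, timepoints, genes = NULL) {
  grp <- timecourse_conditions(x, timepoints)
  missing_tp <- setdiff(timepoints, as.numeric(names(grp)))
  if (length(missing_tp))
    stop("timepoint not present in compendium: ", missing_tp[1L],
         " dpi", call. = FALSE)
  sig <- x$signals
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(sig))
    if (length(unknown))
      stop("unknown gene_id: ", unknown[1L], call. = FALSE)
    sig <- sig[genes, , drop = FALSE]
  }
  means <- vapply(as.character(sort(timepoints)),
                  function(t) rowMeans(sig[, grp[[t]], drop = FALSE]),
                  numeric(nrow(sig)))
  colnames(means) <- as.character(sort(timepoints))
  means
}

#' Temporal activation ratios over the nodule time course
#'
#' Averages replicates per timepoint and expresses each gene's signal
#' at every dpi as a ratio to its signal at the reference dpi (default
#' 14, by which the transcriptome of the family under study is fully
#' activated). Genes with zero reference signal are flagged undefined.
#'
#' @param x A [compendium()].
#' @param timepoints Dpi values to use; all must be present among the
#'   untreated whole-organ dpi conditions (default
#'   `c(0, 3, 4, 6, 10, 14, 28)` intersected with what the compendium
#'   holds).
#' @param reference Reference dpi (default 14).
#' @param genes Optional gene subset.
#' @return An object of class `temporal_ratios`: list with `ratios` and
#'   `means` (gene x timepoint matrices), `timepoints`, `reference`,
#'   `defined`, and `ordering` (per timepoint, gene ids by descending
#'   ratio).
#' @export
temporal_ratios <- function(x, timepoints = NULL, reference = 14,
                            genes = NULL) {
  stopifnot(inherits(x, "compendium"))
  if (is.null(timepoints)) {
    avail <- as.numeric(names(timecourse_conditions(x, unique(
      x$conditions$timepoint[!is.na(x$conditions$timepoint)]))))
    timepoints <- sort(intersect(c(0, 3, 4, 6, 10, 14, 28), avail))
  }
  if (!reference %in% timepoints)
    timepoints <- sort(c(timepoints, reference))
  means <- timecourse_means(x, timepoints, genes)
  ref <- means[, as.character(reference)]
  defined <- ref > 0
  ratios <- means / ref
  ratios[!defined, ] <- NA_real_
  ordering <- lapply(as.data.frame(ratios), function(r) {
    ord <- order(-r, rownames(ratios), na.last = TRUE)
    rownames(ratios)[ord]
  })
  structure(list(ratios = ratios, means = means,
                 timepoints = sort(timepoints), reference = reference,
                 defined = defined, ordering = ordering),
            class = "temporal_ratios")
}

#' @export
print.temporal_ratios <- function(x, ...) {
  cat(sprintf("temporal_ratios: %d genes x %d timepoints (dpi %s), reference %g dpi\n",
              nrow(x$ratios), length(x$timepoints),
              paste(x$timepoints, collapse = "/"), x$reference))
  invisible(x)
}

#' Pearson correlation between timepoint expression profiles
#'
#' Correlates, over a gene subset, the replicate-averaged expression
#' vectors of pairs of timepoints. On the family studied here the
#' pre-activation timepoints (0 and 3 dpi) and the fully activated ones
#' (10 and 14 dpi) each correlate close to 1.
#'
#' @param x A [compendium()].
#' @param timepoints Dpi values (default all available among
#'   0/3/4/6/10/14).
#' @param genes Gene subset (at least 2 genes).
#' @return Symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance vector are `NA`.
#' @export
timepoint_correlation <- function(x, timepoints = c(0, 3, 4, 6, 10, 14),
                                  genes) {
  if (length(genes) < 2L)
    stop("need at least 2 genes for timepoint correlation", call. = FALSE)
  means <- timecourse_means(x, timepoints, genes)
  v <- apply(means, 2L, stats::var)
  r <- suppressWarnings(stats::cor(means))
  r[v == 0, ] <- NA_real_
  r[, v == 0] <- NA_real_
  diag(r)[v > 0] <- 1
  r
}

#' Zone-relative spatial expression profile
#'
#' For the five hand-dissected nodule zone samples (I, II, II-III, III,
#' IV, apical to proximal), averages replicates per zone and expresses
#' each gene as log2(zone signal / mean signal over the five zones).
#' Genes with zero five-zone mean are flagged undefined.
#'
#' @param x A [compendium()].
#' @param genes Optional gene subset.
#' @return Object of class `zone_profile`: list with `profile` (gene x
#'   zone matrix of log2 ratios), `zone_means`, `defined`.
#' @export
zone_relative_profile <- function(x, genes = NULL) {
  stopifnot(inherits(x, "compendium"))
  zones <- c("zone_I", "zone_II", "zone_II_III", "zone_III", "zone_IV")
  m <- x$conditions
  sig <- x$signals
  if (!is.null(genes)) sig <- sig[genes, , drop = FALSE]
  cols <- lapply(zones, function(z) m$condition_id[m$sample_class == z])
  missing_z <- zones[lengths(cols) == 0L]
  if (length(missing_z))
    stop("missing zone sample class: ", missing_z[1L], call. = FALSE)
  zm <- vapply(cols, function(ids) rowMeans(sig[, ids, drop = FALSE]),
               numeric(nrow(sig)))
  colnames(zm) <- zones
  grand <- rowMeans(zm)
  defined <- grand > 0
  prof <- log2(zm / grand)
  prof[!defined, ] <- NA_real_
  structure(list(profile = prof, zone_means = zm, defined = defined),
            class = "zone_profile")
}

#' @export
print.zone_profile <- function(x, ...) {
  cat(sprintf("zone_profile: %d genes x 5 zones (log2 ratio to five-zone mean)\n",
              nrow(x$profile)))
  invisible(x)
}

#' Assign temporal activation waves
#'
#' A gene's activation dpi is the first timepoint among 4, 6, 10 and 14
#' dpi at which its replicate-averaged signal reaches both
#' `activation_fraction` of its 14 dpi level and an absolute floor of
#' `floor_factor` times the background. Wave 1 genes activate at 4 dpi,
#' wave 2 at 6 dpi, wave 3 at 10 or 14 dpi; genes that never pass are
#' unassigned. A gene is `declining` when its signal at the latest
#' available timepoint falls below `decline_fraction` of its temporal
#' maximum, `maintained` otherwise.
#'
#' @param ratios A [temporal_ratios()] object whose timepoints include
#'   4, 6, 10 and the reference 14.
#' @param x The [compendium()] the ratios came from (used for the
#'   background estimate).
#' @param activation_fraction Fraction of the 14 dpi level counting as
#'   activated (default 0.5). Raising it can only delay waves.
#' @param floor_factor Absolute floor in multiples of background
#'   (default 5).
#' @param background Background level; default [estimate_background()].
#' @param decline_fraction Threshold for the declining class
#'   (default 0.5).
#' @return Data frame of class `wave_table`: `gene_id`, `wave`
#'   (`"1"|"2"|"3"|"unassigned"`), `activation_dpi`, `maintenance`.
#' @export
assign_waves <- function(ratios, x, activation_fraction = 0.5,
                         floor_factor = 5, background = NULL,
                         decline_fraction = 0.5) {
  stopifnot(inherits(ratios, "temporal_ratios"))
  need <- c(4, 6, 10, ratios$reference)
  miss <- setdiff(need, ratios$timepoints)
  if (length(miss))
    stop("wave assignment needs timepoint ", miss[1L], " dpi", call. = FALSE)
  if (is.null(background)) background <- estimate_background(x)
  floor_abs <- floor_factor * background

  means <- ratios$means
  ref <- means[, as.character(ratios$reference)]
  scan <- sort(unique(c(4, 6, 10, ratios$reference)))
  act_dpi <- rep(NA_real_, nrow(means))
  for (t in scan) {
    v <- means[, as.character(t)]
    hit <- is.na(act_dpi) & v >= activation_fraction * ref & v >= floor_abs
    act_dpi[hit] <- t
  }
  wave <- rep("unassigned", nrow(means))
  wave[!is.na(act_dpi) & act_dpi == 4] <- "1"
  wave[!is.na(act_dpi) & act_dpi == 6] <- "2"
  wave[!is.na(act_dpi) & act_dpi >= 10] <- "3"

  latest <- means[, as.character(max(ratios$timepoints))]
  peak <- apply(means, 1L, max)
  maintenance <- ifelse(peak > 0 & latest < decline_fraction * peak,
                        "declining", "maintained")

  structure(data.frame(gene_id = rownames(means), wave = wave,
                       activation_dpi = act_dpi, maintenance = maintenance,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("wave_table", "data.frame"),
            activation_fraction = activation_fraction,
            floor = floor_abs)
}

#' Average-linkage (UPGMA) hierarchical clustering with deterministic ties
#'
#' Agglomerative clustering of matrix rows under Euclidean or Pearson
#' (1 - r) distance with average linkage, as used for expression heat
#' maps. Tie-breaking is fully specified so dendrograms are
#' reproducible: among equal-distance merge candidates the pair whose
#' smallest original row index is lowest wins (then the lower remaining
#' index); in the leaf ordering, the subtree containing the smaller
#' minimum index is placed left.
#'
#' @param mat Numeric matrix with at least 2 rows; rownames label the
#'   leaves.
#' @param distance `"euclidean"` or `"pearson"` (1 - Pearson r; rows
#'   with zero variance are rejected with the offending row named).
#' @param linkage Only `"average"` is provided.
#' @return Object of class `upgma_dendrogram`: list with `merge` and
#'   `height` in [stats::hclust()] encoding, `order` (leaf order),
#'   `labels`, `merges` (data frame of (left, right, height) triples on
#'   cluster ids), `dist.method`.
#' @examples
#' m <- matrix(c(0, 1, 10, 11), ncol = 1,
#'             dimnames = list(letters[1:4], NULL))
#' d <- hierarchical_cluster(m)
#' d$height   # 1, 1, 10
#' @export
hierarchical_cluster <- function(mat, distance = c("euclidean", "pearson"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (!identical(linkage, "average"))
    stop("only average linkage (UPGMA) is provided", call. = FALSE)
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("need a matrix with at least 2 rows", call. = FALSE)
  labels <- rownames(mat)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(mat)))
  n <- nrow(mat)

  if (distance == "euclidean") {
    D <- as.matrix(stats::dist(mat, method = "euclidean"))
  } else {
    v <- apply(mat, 1L, stats::var)
    if (any(v == 0))
      stop("zero-variance row under pearson distance: ",
           labels[which(v == 0)[1L]], call. = FALSE)
    D <- 1 - stats::cor(t(mat))
  }
  diag(D) <- Inf

  # active clusters keyed by position; members = original row indices
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)              # hclust encoding: negative = singleton
  active <- rep(TRUE, n + 0L)
  minidx <- seq_len(n)            # smallest original index per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  node_min <- vector("list", n - 1L)  # min original index per internal node

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    h <- min(sub)
    cand <- which(sub == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break on smallest member indices
    a_min <- pmin(minidx[act[cand[, 1L]]], minidx[act[cand[, 2L]]])
    b_min <- pmax(minidx[act[cand[, 1L]]], minidx[act[cand[, 2L]]])
    pick <- order(a_min, b_min)[1L]
    i <- act[cand[pick, 1L]]; j <- act[cand[pick, 2L]]
    if (minidx[j] < minidx[i]) { tmp <- i; i <- j; j <- tmp }

    # Lance-Williams update for average linkage
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- (ni * D[i, act] + nj * D[j, act]) / (ni + nj)

    left <- ids[i]; right <- ids[j]
    # put the child with the smaller min index left
    lm <- minidx[i]; rm <- minidx[j]
    merge[s, ] <- if (lm <= rm) c(left, right) else c(right, left)
    height[s] <- h
    merges[[s]] <- data.frame(left = merge[s, 1L], right = merge[s, 2L],
                              height = h)
    members[[i]] <- c(members[[i]], members[[j]])
    minidx[i] <- min(lm, rm)
    node_min[[s]] <- minidx[i]
    ids[i] <- s
    active[j] <- FALSE
    D[i, act] <- newd; D[act, i] <- newd
    D[i, i] <- Inf
  }

  # leaf order: recursive traversal, smaller-min-index subtree first
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1L]), leaf_order(merge[node, 2L]))
  }
  ord <- leaf_order(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, merges = do.call(rbind, merges),
                 dist.method = distance),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("upgma_dendrogram: %d leaves, %s distance, average linkage\n",
              length(x$labels), x$dist.method))
  cat("leaf order:", paste(utils::head(x$labels[x$order], 10L),
                           collapse = " "),
      if (length(x$labels) > 10L) "...\n" else "\n")
  invisible(x)
}

#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 dist.method = x$dist.method,
                 call = match.call()),
            class = "hclust")
}

#' @export
plot.upgma_dendrogram <- function(x, ...) {
  plot(stats::as.hclust(x), ...)
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Merge heights become branch lengths (via the ape package).
#'
#' @param x An `upgma_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "upgma_dendrogram"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  ape::write.tree(ape::as.phylo(stats::as.hclust(x)), file = path)
  invisible(path)
}

#' Scale a matrix for heat-map display
#'
#' `row_max` divides each row by its maximum (rows with zero maximum
#' are scaled to zeros and flagged); `log2_ratio` is
#' log2(value / row mean), matching the zone-relative profile;
#' `none` is the identity.
#'
#' @param mat Numeric matrix.
#' @param row_scaling One of `"none"`, `"row_max"`, `"log2_ratio"`.
#' @return Scaled matrix; attribute `flagged_rows` names degenerate
#'   rows.
#' @export
heatmap_matrix <- function(mat, row_scaling = c("none", "row_max",
                                                "log2_ratio")) {
  row_scaling <- match.arg(row_scaling)
  flagged <- character(0)
  out <- switch(row_scaling,
    none = mat,
    row_max = {
      mx <- apply(mat, 1L, max)
      flagged <- rownames(mat)[mx == 0]
      res <- mat / ifelse(mx == 0, 1, mx)
      res[mx == 0, ] <- 0
      res
    },
    log2_ratio = {
      mn <- rowMeans(mat)
      flagged <- rownames(mat)[mn == 0]
      res <- log2(mat / mn)
      res[mn == 0, ] <- NA_real_
      res
    })
  attr(out, "flagged_rows") <- flagged
  out
}
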