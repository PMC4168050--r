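#' Tissue aggregation map
#'
#' An ordered assignment of condition ids to named tissue classes.
#' Each condition may appear in at most one tissue, every tissue needs
#' at least one condition, and at least two tissues are required (the
#' entropy of a one-tissue profile is degenerate).
#'
#' @param groups Named list; names are tissue names, elements are
#'   character vectors of condition ids averaged into that tissue.
#' @return An object of class `tissue_map`.
#' @export
tissue_map <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("every tissue must be named", call. = FALSE)
  if (length(groups) < 2L)
    stop("a tissue map needs at least 2 tissues", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("tissue without conditions: ",
         names(groups)[lengths(groups) == 0L][1L], call. = FALSE)
  all_ids <- unlist(groups, use.names = FALSE)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup))
    stop("condition assigned to more than one tissue: ", dup[1L],
         call. = FALSE)
  structure(lapply(groups, as.character), class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf("tissue_map: N = %d tissues, %d conditions\n",
              length(x), sum(lengths(x))))
  for (nm in names(x))
    cat(sprintf("  %-12s %d condition(s)\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Default ten-tissue panel from compendium metadata
#'
#' Reconstructs the atlas-style specificity panel: one tissue per organ
#' among leaf, petiole, stem, bud, flower, seed, pod, root, nodule and
#' mycorrhiza, built from untreated whole-organ conditions only.
#' Nodule uses the 4, 10, 14 and 28 dpi stages; seed all its
#' developmental stages; root its experiments including the 0 dpi
#' nodulation control. Zone, LCM and treated samples are excluded.
#'
#' @param x A [compendium()].
#' @param nodule_dpi Nodule stages averaged into the nodule tissue
#'   (default `c(4, 10, 14, 28)`).
#' @return A [tissue_map()].
#' @export
default_tissue_map <- function(x, nodule_dpi = c(4, 10, 14, 28)) {
  stopifnot(inherits(x, "compendium"))
  m <- x$conditions
  plain <- m$sample_class == "whole_organ" & m$treatment == "none"
  groups <- list()
  for (org in c("leaf", "petiole", "stem", "bud", "flower", "seed", "pod",
                "root", "nodule", "mycorrhiza")) {
    sel <- plain & m$organ == org
    if (org == "nodule")
      sel <- sel & !is.na(m$timepoint) & m$timepoint %in% nodule_dpi
    ids <- m$condition_id[sel]
    if (length(ids)) groups[[org]] <- ids
  }
  tissue_map(groups)
}

#' Read a tissue map from YAML
#'
#' The file is a list of `{tissue: name, conditions: [ids]}` entries.
#'
#' @param path Path to the YAML file.
#' @return A [tissue_map()].
#' @export
read_tissue_map <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- stats::setNames(
    lapply(y, function(e) as.character(e$conditions)),
    vapply(y, function(e) as.character(e$tissue), character(1L)))
  tissue_map(groups)
}

#' Average conditions into a tissue profile
#'
#' Produces the gene x tissue matrix of mean signals W underlying the
#' entropy calculation: each cell is the arithmetic mean of the mapped
#' conditions' signals for that gene.
#'
#' @param x A [compendium()].
#' @param map A [tissue_map()]; all its condition ids must exist in `x`.
#' @return A numeric matrix (genes x tissues) of class `tissue_profile`
#'   with the map attached as attribute `tissue_map`.
#' @export
aggregate_tissues <- function(x, map) {
  stopifnot(inherits(x, "compendium"), inherits(map, "tissue_map"))
  unknown <- setdiff(unlist(map, use.names = FALSE), colnames(x$signals))
  if (length(unknown))
    stop("tissue map names unknown condition: ", unknown[1L], call. = FALSE)
  W <- vapply(map, function(ids)
    rowMeans(x$signals[, ids, drop = FALSE]),
    numeric(nrow(x$signals)))
  dimnames(W) <- list(rownames(x$signals), names(map))
  structure(W, class = c("tissue_profile", "matrix", "array"),
            tissue_map = map)
}

#' Relative expression per tissue
#'
#' Row-normalizes a tissue profile to the relative expression
#' P = W / sum(W) over the N tissues. Genes whose profile sums to zero
#' have no defined relative expression and are flagged.
#'
#' @param profile A `tissue_profile` matrix from [aggregate_tissues()]
#'   (any non-negative gene x tissue matrix works).
#' @return A list of class `relative_profile`: `P` (matrix; `NA` rows
#'   for undefined genes) and `defined` (named logical).
#' @export
relative_expression <- function(profile) {
  W <- unclass(profile)
  if (any(W < 0)) stop("tissue profile must be non-negative", call. = FALSE)
  rs <- rowSums(W)
  defined <- rs > 0
  P <- W / rs
  P[!defined, ] <- NA_real_
  structure(list(P = P, defined = defined), class = "relative_profile")
}

#' Shannon entropy of expression profiles
#'
#' Computes per gene the Shannon entropy E = sum over tissues of
#' -P * log2(P), with the convention 0 * log2(0) = 0. E ranges from 0
#' for a gene expressed in a single tissue to log2(N) for uniform
#' expression over the N tissues; low entropy means high tissue
#' specificity. Genes with undefined relative expression get `NA` and
#' are excluded from ranking. Ranks (1 = most specific) break entropy
#' ties by lexicographic gene id, so orderings are reproducible.
#'
#' @param relative A `relative_profile` from [relative_expression()].
#' @return A data frame of class `entropy_table` with columns
#'   `gene_id`, `entropy`, `rank`, `top_tissue` (argmax tissue, `NA`
#'   when undefined), ordered by rank with undefined genes last.
#'   Attribute `n_tissues` carries N.
#' @examples
#' W <- rbind(u = rep(10, 10), s = c(100, rep(0, 9)))
#' colnames(W) <- paste0("t", 1:10)
#' shannon_entropy(relative_expression(W))
#' @export
shannon_entropy <- function(relative) {
  stopifnot(inherits(relative, "relative_profile"))
  P <- relative$P
  terms <- ifelse(is.na(P) | P == 0, 0, -P * log2(P))
  E <- rowSums(terms)
  E[!relative$defined] <- NA_real_
  gene_id <- rownames(P)
  top <- colnames(P)[apply(P, 1L, function(p)
    if (all(is.na(p))) NA_integer_ else which.max(p))]
  top[!relative$defined] <- NA_character_

  ord <- order(E, gene_id, na.last = TRUE)
  rank <- rep(NA_integer_, length(E))
  rank[ord[seq_len(sum(relative$defined))]] <- seq_len(sum(relative$defined))

  tab <- data.frame(gene_id = gene_id, entropy = E, rank = rank,
                    top_tissue = top, stringsAsFactors = FALSE,
                    row.names = NULL)
  tab <- tab[order(tab$rank, tab$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("entropy_table", "data.frame"),
            n_tissues = ncol(P))
}

#' @export
print.entropy_table <- function(x, ...) {
  n_def <- sum(!is.na(x$entropy))
  cat(sprintf("entropy_table: %d genes (%d ranked), N = %d tissues, max attainable %.4f bits\n",
              nrow(x), n_def, attr(x, "n_tissues"),
              log2(attr(x, "n_tissues"))))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...\n")
  invisible(x)
}

#' @export
plot.entropy_table <- function(x, ...) {
  graphics::hist(x$entropy, breaks = 40,
                 main = "Shannon entropy of tissue profiles",
                 xlab = expression(E[g] ~ "(bits)"), ...)
  graphics::abline(v = log2(attr(x, "n_tissues")), lty = 2)
  invisible(x)
}

#' Select the most tissue-specific genes
#'
#' The k genes of lowest entropy under the stable tie-break of
#' [shannon_entropy()]. The analysis that motivated this package kept
#' the 9,000 most specific of 50,900 probe-sets; for smaller (e.g.
#' synthetic) compendia scale k proportionally.
#'
#' @param table An `entropy_table`.
#' @param k Number of genes to keep; must not exceed the number of
#'   ranked genes.
#' @return Character vector of gene ids, most specific first.
#' @export
select_most_specific <- function(table, k) {
  stopifnot(inherits(table, "entropy_table"))
  n_def <- sum(!is.na(table$rank))
  if (k < 1L || k > n_def)
    stop(sprintf("k must be in [1, %d] (ranked genes), got %s",
                 n_def, format(k)), call. = FALSE)
  table$gene_id[match(seq_len(k), table$rank)]
}
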