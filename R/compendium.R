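#' Expression compendium container
#'
#' A `compendium` bundles a gene x condition matrix of non-negative,
#' linear-scale hybridization signals with a condition metadata table.
#' Rows are probe-sets (genes), columns are experimental conditions;
#' column order always matches the metadata row order.
#'
#' @param signals Numeric matrix, genes in rows (rownames = gene ids),
#'   conditions in columns (colnames = condition ids). All values must be
#'   finite and non-negative; the signal scale is linear (RMA-style
#'   output, background around 9).
#' @param conditions Data frame with one row per condition, in column
#'   order, with columns `condition_id`, `organ`, `treatment`,
#'   `timepoint`, `timepoint_unit`, `sample_class`, `replicate_group`.
#'
#' @return An object of class `compendium`: a list with elements
#'   `signals` and `conditions`.
#'
#' @details Valid organs are leaf, petiole, stem, bud, flower, seed, pod,
#'   root, nodule, mycorrhiza and other. Valid sample classes are
#'   `whole_organ`, the hand-dissected nodule zones `zone_I`, `zone_II`,
#'   `zone_II_III`, `zone_III`, `zone_IV`, and the laser-capture classes
#'   `lcm_M`, `lcm_dIZ`, `lcm_pIZ`, `lcm_IC`, `lcm_UC`. Zone and LCM
#'   classes are only allowed on nodule samples.
#'
#' @examples
#' sig <- matrix(c(9, 1200, 10, 8, 9, 3000), nrow = 3,
#'               dimnames = list(c("g1", "g2", "g3"), c("leaf_1", "nod_1")))
#' meta <- data.frame(condition_id = c("leaf_1", "nod_1"),
#'                    organ = c("leaf", "nodule"), treatment = "none",
#'                    timepoint = c(NA, 14), timepoint_unit = c(NA, "dpi"),
#'                    sample_class = "whole_organ",
#'                    replicate_group = c("leaf", "nod14"))
#' cmp <- compendium(sig, meta)
#' cmp
#' @export
compendium <- function(signals, conditions) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("'signals' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(signals)) || is.null(colnames(signals)))
    stop("'signals' must have gene ids as rownames and condition ids as colnames",
         call. = FALSE)
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  obj <- structure(list(signals = signals, conditions = conditions),
                   class = "compendium")
  validate_compendium(obj)
  obj
}

.ORGANS <- c("leaf", "petiole", "stem", "bud", "flower", "seed", "pod",
             "root", "nodule", "mycorrhiza", "other")
.SAMPLE_CLASSES <- c("whole_organ", "zone_I", "zone_II", "zone_II_III",
                     "zone_III", "zone_IV",
                     "lcm_M", "lcm_dIZ", "lcm_pIZ", "lcm_IC", "lcm_UC")
.META_COLS <- c("condition_id", "organ", "treatment", "timepoint",
                "timepoint_unit", "sample_class", "replicate_group")

#' Validate a compendium object
#'
#' Checks every structural invariant: unique gene and condition ids,
#' finite non-negative signals, metadata columns present, column order
#' identical to metadata order, legal organ / sample-class vocabulary,
#' and zone or LCM classes restricted to nodule samples.
#'
#' @param x A `compendium`.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending id or cell.
#' @export
validate_compendium <- function(x) {
  sig <- x$signals
  meta <- x$conditions

  dup <- rownames(sig)[duplicated(rownames(sig))]
  if (length(dup))
    stop("duplicate gene_id: ", dup[1L], call. = FALSE)
  dup <- colnames(sig)[duplicated(colnames(sig))]
  if (length(dup))
    stop("duplicate condition_id: ", dup[1L], call. = FALSE)

  bad <- which(!is.finite(sig) | sig < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid signal at gene '%s', condition '%s': %s",
                 rownames(sig)[bad[1L, 1L]], colnames(sig)[bad[1L, 2L]],
                 format(sig[bad[1L, , drop = FALSE]])), call. = FALSE)

  miss <- setdiff(.META_COLS, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- meta$condition_id[duplicated(meta$condition_id)]
  if (length(dup))
    stop("duplicate condition_id in metadata: ", dup[1L], call. = FALSE)

  orphan <- setdiff(meta$condition_id, colnames(sig))
  if (length(orphan))
    stop("metadata row without matrix column: ", orphan[1L], call. = FALSE)
  orphan <- setdiff(colnames(sig), meta$condition_id)
  if (length(orphan))
    stop("matrix column without metadata: ", orphan[1L], call. = FALSE)
  if (!identical(colnames(sig), meta$condition_id))
    stop("condition order in matrix and metadata differs", call. = FALSE)

  bad <- setdiff(unique(meta$organ), .ORGANS)
  if (length(bad))
    stop("unknown organ: ", bad[1L], call. = FALSE)
  bad <- setdiff(unique(meta$sample_class), .SAMPLE_CLASSES)
  if (length(bad))
    stop("unknown sample_class: ", bad[1L], call. = FALSE)
  zoned <- meta$sample_class != "whole_organ"
  if (any(zoned & meta$organ != "nodule"))
    stop("zone/LCM sample_class on non-nodule condition: ",
         meta$condition_id[which(zoned & meta$organ != "nodule")[1L]],
         call. = FALSE)

  tp <- meta$timepoint
  if (any(!is.na(tp) & (tp < 0 | !is.finite(tp))))
    stop("negative or non-finite timepoint for condition: ",
         meta$condition_id[which(!is.na(tp) & (tp < 0 | !is.finite(tp)))[1L]],
         call. = FALSE)
  invisible(x)
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d genes x %d conditions\n",
              nrow(x$signals), ncol(x$signals)))
  org <- table(x$conditions$organ)
  cat("organs:", paste(sprintf("%s(%d)", names(org), org), collapse = " "),
      "\n")
  cat(sprintf("signal range: %.4g .. %.4g\n",
              min(x$signals), max(x$signals)))
  invisible(x)
}

#' @export
dim.compendium <- function(x) dim(x$signals)

#' Read an expression compendium from TSV files
#'
#' The matrix file is a UTF-8 TSV whose first column is headed `gene_id`
#' and whose remaining headers are condition ids; the metadata file has
#' one row per condition with the columns documented in [compendium()].
#' Empty cells in the matrix are an error: the source compendium is
#' complete, and missing values only ever arise in derived outputs.
#'
#' @param matrix_path Path to the signal matrix TSV.
#' @param metadata_path Path to the condition metadata TSV.
#' @return A validated [compendium()].
#' @export
read_compendium <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL, fileEncoding = "UTF-8")
  if (!identical(names(raw)[1L], "gene_id"))
    stop("matrix file must have 'gene_id' as its first column header",
         call. = FALSE)
  gene_ids <- raw[[1L]]
  cond_ids <- names(raw)[-1L]
  sig <- matrix(NA_real_, nrow = length(gene_ids), ncol = length(cond_ids),
                dimnames = list(gene_ids, cond_ids))
  for (j in seq_along(cond_ids)) {
    col <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) | trimws(col) == "")
    if (length(bad))
      stop(sprintf("non-numeric or empty cell at gene '%s', condition '%s': '%s'",
                   gene_ids[bad[1L]], cond_ids[j], col[bad[1L]]),
           call. = FALSE)
    neg <- which(val < 0)
    if (length(neg))
      stop(sprintf("negative signal at gene '%s', condition '%s': %s",
                   gene_ids[neg[1L]], cond_ids[j], col[neg[1L]]),
           call. = FALSE)
    sig[, j] <- val
  }
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if ("timepoint" %in% names(meta))
    meta$timepoint <- suppressWarnings(as.numeric(meta$timepoint))
  # put metadata rows into matrix column order after cross-checking ids
  orphan <- setdiff(meta$condition_id, cond_ids)
  if (length(orphan))
    stop("metadata row without matrix column: ", orphan[1L], call. = FALSE)
  orphan <- setdiff(cond_ids, meta$condition_id)
  if (length(orphan))
    stop("matrix column without metadata: ", orphan[1L], call. = FALSE)
  meta <- meta[match(cond_ids, meta$condition_id), , drop = FALSE]
  rownames(meta) <- NULL
  compendium(sig, meta)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `family`, `label`. Family is one of
#' `NCR`, `senescence_marker`, `bacterial_marker`, `other`.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with unique gene ids.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("gene_id", "family", "label")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in annotation: ", dup[1L], call. = FALSE)
  bad <- setdiff(unique(ann$family),
                 c("NCR", "senescence_marker", "bacterial_marker", "other"))
  if (length(bad))
    stop("unknown family: ", bad[1L], call. = FALSE)
  ann
}

#' Write a result table as TSV
#'
#' Deterministic serialization used by every stage: columns in the order
#' given, rows in the order given, reals at 12 significant digits with a
#' `.` decimal separator, `NA` for missing derived values. Re-reading
#' with [read_result_table()] reproduces string and integer columns
#' bit-exactly and reals to 12 significant digits. An empty table writes
#' a header-only file.
#'
#' @param rows Data frame (possibly zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- vapply(v, function(x) {
        if (is.na(x)) NA_character_
        else format(x, digits = 12L, scientific = FALSE, trim = TRUE,
                    decimal.mark = ".")
      }, character(1L))
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame; numeric-looking columns are converted back to
#'   numeric, `NA` cells to `NA`.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    fileEncoding = "UTF-8")
}

#' Write a compendium to a pair of TSV files
#'
#' Inverse of [read_compendium()].
#'
#' @param x A [compendium()].
#' @param matrix_path Output path for the signal matrix.
#' @param metadata_path Output path for the condition metadata.
#' @return `matrix_path`, invisibly.
#' @export
write_compendium <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "compendium"))
  tab <- data.frame(gene_id = rownames(x$signals),
                    as.data.frame(x$signals, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_table(tab, matrix_path)
  write_table(x$conditions, metadata_path)
  invisible(matrix_path)
}
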