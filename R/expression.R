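# FPKM expression matrices over monosaccharide growth conditions: reading,
# replicate collapsing, low-expression filtering, per-substrate summaries.

#' Default monosaccharide condition set
#'
#' The nine monosaccharide growth conditions used for transcriptome profiling
#' of plant-biomass-degrading fungi, in their conventional order.
#'
#' @return Character vector of nine condition names.
#' @export
monosaccharide_conditions <- function() {
  c("D-glucose", "D-fructose", "D-galactose", "D-mannose", "L-rhamnose",
    "D-xylose", "L-arabinose", "D-galacturonic acid", "D-glucuronic acid")
}

#' Read an FPKM expression matrix with sample metadata
#'
#' The matrix TSV has gene rows (first column `gene_id`) and one column per
#' sample; the metadata TSV has columns `sample_id`, `condition`, `replicate`.
#' Every matrix column must be described in the metadata, values must be
#' non-negative, gene ids unique, and (condition, replicate) pairs unique.
#' Sample columns are reordered to metadata order.
#'
#' @param matrix_path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @param conditions Optional condition vocabulary; when given, the metadata's
#'   condition set must equal it. `NULL` (default) accepts the conditions
#'   found in the metadata.
#' @return An `expression_matrix`: list with `values` (numeric gene x sample
#'   matrix) and `meta` (data frame `sample_id`, `condition`, `replicate`).
#' @export
read_expression <- function(matrix_path, meta_path, conditions = NULL) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE, quote = "",
                            comment.char = "#", fileEncoding = "UTF-8",
                            check.names = FALSE)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  mat <- utils::read.delim(matrix_path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", fileEncoding = "UTF-8",
                           check.names = FALSE)
  genes <- as.character(mat[[1L]])
  vals <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  expression_matrix(vals, meta, conditions = conditions)
}

#' @rdname read_expression
#' @param values Numeric gene x sample matrix with dimnames.
#' @param meta Sample metadata data frame.
#' @export
expression_matrix <- function(values, meta, conditions = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$replicate <- as.integer(meta$replicate)
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1L))
    stop("replicate must be a positive integer")
  if (anyDuplicated(paste(meta$condition, meta$replicate)))
    stop("duplicate (condition, replicate) pairs in metadata")
  if (!is.null(conditions) && !setequal(unique(meta$condition), conditions))
    stop("metadata condition set does not match the configured vocabulary")
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta))
    stop("sample column(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  missing_col <- setdiff(meta$sample_id, colnames(values))
  if (length(missing_col))
    stop("metadata sample(s) absent from matrix: ",
         paste(missing_col, collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative FPKM at gene '", rownames(values)[neg[1L, 1L]],
         "', sample '", colnames(values)[neg[1L, 2L]], "'")
  values <- values[, meta$sample_id, drop = FALSE]
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("FPKM matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$meta$condition)), " conditions)\n",
      sep = "")
  invisible(x)
}

#' Collapse replicates to per-condition means
#'
#' Averages FPKM arithmetically over the replicates of each condition,
#' yielding the gene x condition matrix the specificity index operates on.
#' Condition order follows first appearance in the metadata.
#'
#' @param em An `expression_matrix`.
#' @return A `condition_matrix`: numeric gene x condition matrix (class
#'   `condition_matrix`).
#' @export
collapse_replicates <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  conds <- unique(em$meta$condition)
  if (length(conds) < 2L)
    stop("need at least 2 conditions (specificity index divides by n - 1)")
  out <- vapply(conds, function(cc) {
    cols <- em$meta$sample_id[em$meta$condition == cc]
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(rownames(em$values),
                                                           conds))
  class(out) <- c("condition_matrix", class(out))
  out
}

#' @rdname collapse_replicates
#' @param values Numeric gene x condition matrix.
#' @export
condition_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("need at least 2 conditions")
  if (any(values < 0)) stop("FPKM values must be non-negative")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  class(values) <- c("condition_matrix", class(values))
  values
}

#' Filter extremely low-expressed genes
#'
#' Removes genes whose maximum FPKM over all conditions is below the
#' threshold; a gene at exactly the threshold is retained ("less than"
#' read strictly). Gene order is preserved; the filter is idempotent.
#'
#' @param cm A `condition_matrix`.
#' @param fpkm_threshold Non-negative FPKM cutoff (default 10).
#' @return The filtered `condition_matrix`.
#' @export
filter_low_expression <- function(cm, fpkm_threshold = 10) {
  stopifnot(fpkm_threshold >= 0)
  keep <- apply(unclass(cm), 1L, max) >= fpkm_threshold
  out <- unclass(cm)[keep, , drop = FALSE]
  class(out) <- c("condition_matrix", class(out))
  out
}

#' Per-substrate, per-condition expression distribution summary
#'
#' For each polysaccharide substrate, pools the expression values (one per
#' gene and condition) of the genes whose annotated family maps to that
#' substrate, and summarises each condition's distribution by quartiles,
#' Tukey whiskers and 1.5 x IQR outliers — the numbers behind a grouped
#' boxplot of CAZyme expression per substrate. Genes of multifunctional
#' families appear in every substrate group their family maps to.
#'
#' @param cm A `condition_matrix`.
#' @param annotations Data frame `species`(optional), `gene_id`, `family`
#'   covering a subset of the matrix genes.
#' @param catalog A `cazy_catalog`.
#' @return Data frame with columns `substrate`, `condition`, `n_genes`, `q1`,
#'   `median`, `q3`, `whisker_lo`, `whisker_hi`, `outlier_ids`
#'   (comma-joined gene ids; `""` when none). Substrate/condition pairs with
#'   zero genes get an `n_genes = 0` row with `NA` summaries.
#' @export
group_expression_summary <- function(cm, annotations, catalog) {
  annotations <- validate_annotations(annotations)
  annotations <- annotations[annotations$gene_id %in% rownames(cm), ,
                             drop = FALSE]
  subs <- substrate_vocabulary()
  conds <- colnames(cm)
  rows <- vector("list", length(subs) * length(conds))
  k <- 0L
  for (p in subs) {
    fams <- families_for_substrate(catalog, p)
    genes <- unique(annotations$gene_id[annotations$family %in% fams])
    for (cc in conds) {
      k <- k + 1L
      if (!length(genes)) {
        rows[[k]] <- data.frame(substrate = p, condition = cc, n_genes = 0L,
                                q1 = NA_real_, median = NA_real_,
                                q3 = NA_real_, whisker_lo = NA_real_,
                                whisker_hi = NA_real_, outlier_ids = "",
                                stringsAsFactors = FALSE)
        next
      }
      v <- unclass(cm)[genes, cc]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3L] - q[1L]
      lo_f <- q[1L] - 1.5 * iqr
      hi_f <- q[3L] + 1.5 * iqr
      inside <- v >= lo_f & v <= hi_f
      out_ids <- genes[!inside]
      rows[[k]] <- data.frame(
        substrate = p, condition = cc, n_genes = length(genes),
        q1 = q[1L], median = q[2L], q3 = q[3L],
        whisker_lo = if (any(inside)) min(v[inside]) else NA_real_,
        whisker_hi = if (any(inside)) max(v[inside]) else NA_real_,
        outlier_ids = paste(sort(out_ids), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
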