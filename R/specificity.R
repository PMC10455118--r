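# Sugar specificity index (SSI) and sugar-specific gene (SSG) classification.
#
# SSI is a tau-type expression-specificity statistic: with per-condition
# expression x_1..x_n (n >= 2) and normalised values xhat_i = x_i / max_j x_j,
#
#   SSI = sum_{i=1..n} (1 - xhat_i) / (n - 1)
#
# SSI = 0 for perfectly uniform expression, 1 for expression confined to a
# single condition.

#' Sugar specificity index
#'
#' Computes the specificity of an expression profile across n >= 2 growth
#' conditions: the mean shortfall from maximal expression,
#' \eqn{SSI = \sum_i (1 - x_i / \max_j x_j) / (n - 1)}. The statistic lies in
#' \[0, 1\], is invariant to rescaling of the profile, equals 0 iff every
#' condition sits at the maximum, and equals 1 iff exactly one condition is
#' non-zero.
#'
#' @param x Non-negative numeric vector of per-condition expression (length
#'   >= 2, at least one positive entry).
#' @return The index, a number in \[0, 1\].
#' @examples
#' ssi(c(10, 5, 0, 0))  # 5/6
#' @export
ssi <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("x must be a numeric vector of length >= 2")
  if (anyNA(x) || any(x < 0)) stop("x must be non-negative and complete")
  mx <- max(x)
  if (mx == 0) stop("specificity index undefined for an all-zero profile")
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Specificity classification thresholds
#'
#' @param ssi_threshold SSI above which (strictly) a gene is called
#'   sugar-specific. Default 0.7.
#' @param fpkm_threshold Minimum (inclusive) maximum FPKM for a gene to be
#'   eligible; genes whose maximum over conditions is below it are treated as
#'   too lowly expressed. Default 10.
#' @param condition_order Optional condition ordering used to break exact
#'   ties when assigning the inducing sugar; defaults to the matrix's column
#'   order.
#' @return A `specificity_config` list.
#' @export
specificity_config <- function(ssi_threshold = 0.7, fpkm_threshold = 10,
                               condition_order = NULL) {
  stopifnot(ssi_threshold >= 0, ssi_threshold <= 1, fpkm_threshold >= 0)
  structure(list(ssi_threshold = ssi_threshold,
                 fpkm_threshold = fpkm_threshold,
                 condition_order = condition_order),
            class = "specificity_config")
}

#' Inducing sugar of an expression profile
#'
#' The condition with the highest expression. Exact ties are broken in favour
#' of the earliest condition in `condition_order` and flagged.
#'
#' @param x Named non-negative numeric vector (names = conditions).
#' @param condition_order Character vector giving the tie-break order;
#'   defaults to `names(x)`.
#' @return List with `condition` (`NA` for an all-zero profile) and `tie`
#'   (logical).
#' @export
inducing_sugar <- function(x, condition_order = names(x)) {
  stopifnot(!is.null(names(x)))
  if (max(x) == 0) return(list(condition = NA_character_, tie = FALSE))
  at_max <- names(x)[x == max(x)]
  ord <- c(condition_order, setdiff(names(x), condition_order))
  list(condition = ord[min(match(at_max, ord))],
       tie = length(at_max) > 1L)
}

#' Classify sugar-specific genes
#'
#' Computes one specificity record per gene of a condition matrix: the sugar
#' specificity index, the maximum FPKM, the inducing sugar (condition of
#' maximal expression), and the SSG call. A gene is a sugar-specific gene
#' (SSG) when its SSI strictly exceeds `ssi_threshold` and its maximum FPKM
#' is at least `fpkm_threshold`. All-zero genes get an `NA` index and are
#' never SSGs, so the output has exactly one row per input gene.
#'
#' @param cm A `condition_matrix` (genes x conditions, mean FPKM).
#' @param config A [specificity_config()].
#' @return An object of class `ssg_classification`: a data frame with columns
#'   `gene_id`, `ssi`, `max_fpkm`, `inducing_condition`, `tie`, `is_ssg`,
#'   carrying the config and condition set as attributes. Methods: `print`,
#'   `summary`, `coef` (named SSI vector).
#' @examples
#' cm <- condition_matrix(matrix(c(100, 1, 5, 5), 2, byrow = TRUE,
#'                        dimnames = list(c("a", "b"), c("c1", "c2"))))
#' classify_ssg(cm)
#' @export
classify_ssg <- function(cm, config = specificity_config()) {
  stopifnot(inherits(config, "specificity_config"))
  vals <- unclass(cm)
  if (ncol(vals) < 2L) stop("need at least 2 conditions")
  ord <- config$condition_order
  if (is.null(ord)) ord <- colnames(vals)
  n <- nrow(vals)
  ssi_v <- rep(NA_real_, n)
  maxf <- apply(vals, 1L, max)
  ind <- rep(NA_character_, n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    if (maxf[i] > 0) {
      ssi_v[i] <- ssi(vals[i, ])
      is_ <- inducing_sugar(vals[i, ], condition_order = ord)
      ind[i] <- is_$condition
      tie[i] <- is_$tie
    }
  }
  is_ssg <- !is.na(ssi_v) & ssi_v > config$ssi_threshold &
    maxf >= config$fpkm_threshold
  out <- data.frame(gene_id = rownames(vals), ssi = ssi_v, max_fpkm = maxf,
                    inducing_condition = ind, tie = tie, is_ssg = is_ssg,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ssg_classification", "data.frame"),
            config = config, conditions = colnames(vals))
}

#' @export
print.ssg_classification <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Sugar-specificity classification of ", nrow(x), " genes over ",
      length(attr(x, "conditions")), " conditions\n", sep = "")
  cat("  SSI > ", cfg$ssi_threshold, " and max FPKM >= ", cfg$fpkm_threshold,
      ": ", sum(x$is_ssg), " sugar-specific genes\n", sep = "")
  invisible(x)
}

#' @rdname classify_ssg
#' @param object An `ssg_classification`.
#' @param ... Unused.
#' @export
summary.ssg_classification <- function(object, ...) {
  ssgs <- object[object$is_ssg, , drop = FALSE]
  by_cond <- table(factor(ssgs$inducing_condition,
                          levels = attr(object, "conditions")))
  structure(list(n_genes = nrow(object), n_ssg = nrow(ssgs),
                 n_low = sum(object$max_fpkm < attr(object,
                                                    "config")$fpkm_threshold),
                 ssi_quartiles = stats::quantile(object$ssi, na.rm = TRUE),
                 ssg_by_condition = by_cond,
                 config = attr(object, "config")),
            class = "summary.ssg_classification")
}

#' @export
print.summary.ssg_classification <- function(x, ...) {
  cat("Genes: ", x$n_genes, "  SSGs: ", x$n_ssg,
      "  below FPKM threshold: ", x$n_low, "\n", sep = "")
  cat("SSI quartiles:\n")
  print(round(x$ssi_quartiles, 3))
  cat("SSGs per inducing sugar:\n")
  print(x$ssg_by_condition)
  invisible(x)
}

#' @rdname classify_ssg
#' @export
coef.ssg_classification <- function(object, ...) {
  stats::setNames(object$ssi, object$gene_id)
}

#' Cross-tabulate SSGs by substrate and inducing sugar
#'
#' Counts, for every polysaccharide substrate and every condition, the
#' sugar-specific genes induced on that condition whose annotated CAZy family
#' maps to that substrate. Genes of multifunctional families contribute to
#' each substrate their family maps to; SSGs without an annotation (or with
#' an off-catalog family) are tallied in an `other` row.
#'
#' @param records An `ssg_classification` (or compatible data frame).
#' @param annotations Data frame with `gene_id`, `family` (and optionally
#'   `species`).
#' @param catalog A `cazy_catalog`.
#' @return Integer matrix: substrate rows (7 substrates + `other`) x
#'   condition columns.
#' @export
ssg_crosstab <- function(records, annotations, catalog) {
  annotations <- validate_annotations(annotations)
  conds <- attr(records, "conditions")
  if (is.null(conds))
    conds <- sort(unique(stats::na.omit(records$inducing_condition)))
  subs <- c(substrate_vocabulary(), "other")
  out <- matrix(0L, length(subs), length(conds),
                dimnames = list(subs, conds))
  ssgs <- records[records$is_ssg, , drop = FALSE]
  fam_of <- stats::setNames(annotations$family, annotations$gene_id)
  for (i in seq_len(nrow(ssgs))) {
    cc <- ssgs$inducing_condition[i]
    fam <- unname(fam_of[ssgs$gene_id[i]])
    ps <- if (is.na(fam)) character() else substrates_of(catalog, fam)
    if (!length(ps)) ps <- "other"
    out[ps, cc] <- out[ps, cc] + 1L
  }
  out
}
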