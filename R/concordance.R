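# Ordinal growth profiles and repertoire-growth concordance.
#
# Growth on each carbon source is scored on a 4-level ordinal scale:
# 0 = no growth (same as the no-carbon control), 1 = poor, 2 = moderate,
# 3 = good, with growth on D-glucose serving as the internal reference.

#' Read ordinal growth profiles
#'
#' TSV with columns `species`, `carbon_source`, `score` (integers 0-3).
#' Carbon sources outside the polysaccharide catalog (monosaccharides,
#' disaccharides) are kept verbatim; a D-glucose reference row is required
#' for every species.
#'
#' @param path Path to the growth TSV.
#' @param reference Name of the reference carbon source (default
#'   `"D-glucose"`).
#' @return Data frame `species`, `carbon_source`, `score` of class
#'   `growth_profiles`.
#' @export
read_growth <- function(path, reference = "D-glucose") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  req <- c("species", "carbon_source", "score")
  if (!all(req %in% names(df)))
    stop("growth table must have columns: ", paste(req, collapse = ", "))
  growth_profiles(df[, req], reference = reference)
}

#' @rdname read_growth
#' @param df Data frame with the growth columns.
#' @export
growth_profiles <- function(df, reference = "D-glucose") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  sc <- suppressWarnings(as.integer(df$score))
  if (any(is.na(sc)) || any(sc < 0L) || any(sc > 3L))
    stop("growth scores must be integers in 0..3 (0 = no growth, 3 = good)")
  df$score <- sc
  if (anyDuplicated(paste(df$species, df$carbon_source)))
    stop("duplicate (species, carbon_source) rows")
  no_ref <- setdiff(unique(df$species),
                    df$species[df$carbon_source == reference])
  if (length(no_ref))
    stop("missing ", reference, " reference row for: ",
         paste(no_ref, collapse = ", "))
  structure(df, class = c("growth_profiles", "data.frame"),
            reference = reference)
}

#' Map growth carbon sources to catalog substrates
#'
#' Translates plate carbon sources (e.g. "beechwood xylan", "guar gum",
#' "maltose") to the seven polysaccharide substrates via a two-column mapping
#' table. Unmapped carbon sources are dropped; when several carbon sources
#' map to one substrate (e.g. apple and citrus pectin) the maximum growth
#' score is kept, reflecting the species' best demonstrated use of that
#' polysaccharide.
#'
#' @param growth A `growth_profiles` table.
#' @param map Data frame `carbon_source`, `substrate`, or a path to such a
#'   TSV. `NULL` loads the packaged mapping.
#' @return Data frame `species`, `substrate`, `score`.
#' @export
map_growth_substrates <- function(growth, map = NULL) {
  if (is.null(map))
    map <- system.file("extdata", "growth_substrate_map.tsv",
                       package = "cazyspec", mustWork = TRUE)
  if (is.character(map))
    map <- utils::read.delim(map, stringsAsFactors = FALSE, quote = "",
                             comment.char = "#", fileEncoding = "UTF-8")
  stopifnot(all(c("carbon_source", "substrate") %in% names(map)))
  bad <- setdiff(unique(map$substrate), substrate_vocabulary())
  if (length(bad))
    stop("unknown substrate(s) in mapping: ", paste(bad, collapse = ", "))
  m <- merge(as.data.frame(growth), map, by = "carbon_source")
  if (!nrow(m))
    return(data.frame(species = character(), substrate = character(),
                      score = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(score ~ species + substrate, data = m, FUN = max)
  agg[order(agg$species, agg$substrate), c("species", "substrate", "score")]
}

#' Rank concordance between repertoire and growth
#'
#' For each species, correlates per-substrate CAZyme gene totals with ordinal
#' growth scores across the substrates present in both tables, using the
#' tie-adjusted (midrank) Spearman rank correlation. Species with fewer than
#' `min_substrates` shared substrates get an `NA` correlation with a reason.
#'
#' @param totals Species x substrate count matrix from [substrate_totals()].
#' @param growth_sub Data frame `species`, `substrate`, `score` from
#'   [map_growth_substrates()].
#' @param min_substrates Minimum shared substrates to evaluate (default 3).
#' @return Data frame `species`, `rank_correlation`, `n_substrates`, `note`.
#' @export
rank_concordance <- function(totals, growth_sub, min_substrates = 3L) {
  species <- rownames(totals)
  res <- lapply(species, function(s) {
    g <- growth_sub[growth_sub$species == s, , drop = FALSE]
    shared <- intersect(colnames(totals), g$substrate)
    if (length(shared) < min_substrates)
      return(data.frame(species = s, rank_correlation = NA_real_,
                        n_substrates = length(shared),
                        note = sprintf("only %d shared substrates (need %d)",
                                       length(shared), min_substrates),
                        stringsAsFactors = FALSE))
    x <- totals[s, shared]
    y <- g$score[match(shared, g$substrate)]
    rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    data.frame(species = s, rank_correlation = rho,
               n_substrates = length(shared), note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag repertoire-growth discordances
#'
#' A (species, substrate) pair is discordant when genomic potential and
#' observed growth point in opposite directions: the species' gene total for
#' the substrate is at or below the `low_quantile` of that substrate's totals
#' across species while growth is moderate-to-good (score >= 2)
#' (`repertoire_low_growth_high`), or the total is at or above the
#' `high_quantile` while growth is at most poor (score <= 1)
#' (`repertoire_high_growth_low`). The two directions are mutually exclusive
#' for a given pair.
#'
#' @param totals Species x substrate count matrix.
#' @param growth_sub Data frame `species`, `substrate`, `score`.
#' @param high_quantile,low_quantile Quantile cutoffs in (0, 1),
#'   `low_quantile < high_quantile`; defaults 0.75 and 0.25.
#' @return Data frame `species`, `substrate`, `direction`, `total`, `score`.
#' @export
flag_discordant <- function(totals, growth_sub, high_quantile = 0.75,
                            low_quantile = 0.25) {
  stopifnot(low_quantile > 0, high_quantile < 1, low_quantile < high_quantile)
  out <- list()
  for (p in intersect(colnames(totals), unique(growth_sub$substrate))) {
    qs <- stats::quantile(totals[, p], c(low_quantile, high_quantile),
                          names = FALSE, type = 7)
    for (s in rownames(totals)) {
      row <- growth_sub[growth_sub$species == s & growth_sub$substrate == p, ]
      if (!nrow(row)) next
      dir <- NULL
      if (totals[s, p] <= qs[1L] && row$score >= 2L)
        dir <- "repertoire_low_growth_high"
      else if (totals[s, p] >= qs[2L] && row$score <= 1L)
        dir <- "repertoire_high_growth_low"
      if (!is.null(dir))
        out[[length(out) + 1L]] <- data.frame(
          species = s, substrate = p, direction = dir,
          total = totals[s, p], score = row$score,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(species = character(), substrate = character(),
                      direction = character(), total = integer(),
                      score = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
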