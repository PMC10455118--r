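#' @keywords internal
"_PACKAGE"

# Enzyme-class vocabulary of the catalog. FAE (feruloyl esterase) is carried
# as a pseudo-family with no number so it counts and cross-tabulates like any
# CAZy family. The parser additionally accepts GT (glycosyltransferases) so
# that annotation inputs covering the whole CAZy database can be read; GT
# families are never catalog members and end up in the off-catalog side table.
.cazy_classes <- c("GH", "CE", "PL", "AA", "FAE")
.parse_classes <- c("GH", "GT", "CE", "PL", "AA", "FAE")

# The seven plant polysaccharides covered by the catalog.
.substrates <- c("cellulose", "xylan", "xyloglucan", "mannan", "pectin",
                 "starch", "inulin")

#' Substrate vocabulary
#'
#' The seven plant polysaccharides the packaged catalog maps CAZy families to:
#' cellulose, xylan, xyloglucan, mannan, pectin, starch and inulin.
#'
#' @return Character vector of substrate names.
#' @export
substrate_vocabulary <- function() .substrates

#' Parse a CAZy (sub-)family label
#'
#' Parses labels in the CAZy convention: enzyme class (`GH`, `CE`, `PL`, `AA`),
#' family number, and optional underscore-separated subfamily (e.g. `"GH5_7"`,
#' `"AA3_1"`). The label `"FAE"` denotes the feruloyl-esterase pseudo-family,
#' which has neither family number nor subfamily.
#'
#' @param label Character vector of family labels.
#' @return An object of class `family_key`: a data frame with columns
#'   `class`, `family` (integer, `NA` for FAE) and `subfamily` (integer or
#'   `NA`). `format()`/`as.character()` round-trip to the canonical label.
#' @examples
#' parse_family_key(c("GH5_7", "CE8", "FAE"))
#' @export
parse_family_key <- function(label) {
  if (length(label) == 0L || any(!nzchar(label)) || anyNA(label))
    stop("family labels must be non-empty strings")
  label <- trimws(label)
  m <- regmatches(label,
                  regexec("^(GH|GT|CE|PL|AA)([0-9]+)(_([0-9]+))?$", label))
  cls <- character(length(label))
  fam <- sub <- rep(NA_integer_, length(label))
  for (i in seq_along(label)) {
    if (label[i] == "FAE") {
      cls[i] <- "FAE"
    } else if (length(m[[i]])) {
      cls[i] <- m[[i]][2]
      fam[i] <- as.integer(m[[i]][3])
      if (nzchar(m[[i]][5])) sub[i] <- as.integer(m[[i]][5])
    } else {
      stop("malformed CAZy family label: '", label[i], "'")
    }
  }
  out <- data.frame(class = cls, family = fam, subfamily = sub,
                    stringsAsFactors = FALSE)
  class(out) <- c("family_key", "data.frame")
  out
}

#' @rdname parse_family_key
#' @param x A `family_key` object.
#' @param ... Unused.
#' @export
format.family_key <- function(x, ...) {
  ifelse(x$class == "FAE", "FAE",
         paste0(x$class, x$family,
                ifelse(is.na(x$subfamily), "", paste0("_", x$subfamily))))
}

#' @rdname parse_family_key
#' @export
as.character.family_key <- function(x, ...) format(x)

#' @export
print.family_key <- function(x, ...) {
  cat("<family_key> ", paste(format(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Drop the subfamily component: "GH5_7" -> "GH5". Vectorised on labels.
roll_up_family <- function(label) sub("_[0-9]+$", "", label)

#' Load a CAZy family-to-substrate catalog
#'
#' Reads a catalog mapping CAZy (sub-)families through enzyme-activity codes
#' to plant polysaccharide substrates. With no `path`, the packaged catalog
#' reconstructed from the comparative-genomics literature on fungal plant
#' biomass degradation is returned. The file dialect is UTF-8 TSV with a
#' header row (`family`, `activity_code`, `substrate`, optional `provenance`);
#' lines starting with `#` are ignored.
#'
#' @param path Optional path to a catalog TSV. `NULL` loads the packaged one.
#' @return An object of class `cazy_catalog`: a data frame with columns
#'   `family`, `activity_code`, `substrate`, `provenance`.
#' @examples
#' cat <- load_catalog()
#' nrow(cat)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cazy_catalog.tsv", package = "cazyspec",
                        mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8")
  req <- c("family", "activity_code", "substrate")
  if (!all(req %in% names(df)))
    stop("catalog must have columns: ", paste(req, collapse = ", "))
  if (is.null(df$provenance)) df$provenance <- ""
  bad <- setdiff(unique(df$substrate), .substrates)
  if (length(bad))
    stop("unknown substrate(s) in catalog: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.substrates, collapse = ", "), ")")
  # canonicalise labels; errors here name the offending label
  keys <- parse_family_key(df$family)
  off_class <- setdiff(unique(keys$class), .cazy_classes)
  if (length(off_class))
    stop("catalog entries restricted to enzyme classes ",
         paste(.cazy_classes, collapse = ", "), "; found: ",
         paste(off_class, collapse = ", "))
  df$family <- format(keys)
  key <- paste(df$family, df$activity_code, df$substrate)
  if (anyDuplicated(key))
    stop("duplicate catalog entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df <- df[, c("family", "activity_code", "substrate", "provenance")]
  class(df) <- c("cazy_catalog", "data.frame")
  df
}

#' @export
print.cazy_catalog <- function(x, ...) {
  cat("CAZy family-substrate catalog: ", nrow(x), " entries, ",
      length(unique(x$family)), " (sub-)families, ",
      length(unique(x$substrate)), " substrates\n", sep = "")
  tab <- table(x$substrate)[.substrates]
  cat("  entries per substrate: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Substrates degraded by a CAZy family
#'
#' Looks up the polysaccharide substrates a family is mapped to. A
#' subfamily-level query (e.g. `GH13_40`) that has no subfamily entry falls
#' back to the plain-family entries; a family-level query (e.g. `GH5`) with no
#' family-level entry returns the union over that family's subfamily entries.
#' Unknown families yield an empty set, not an error.
#'
#' @param catalog A `cazy_catalog`.
#' @param family A single family label (or `family_key` row).
#' @return Character vector of substrates (possibly empty), in the canonical
#'   substrate order.
#' @examples
#' substrates_of(load_catalog(), "GH12")
#' @export
substrates_of <- function(catalog, family) {
  if (inherits(family, "family_key")) family <- format(family)
  stopifnot(length(family) == 1L)
  key <- format(parse_family_key(family))  # validates
  hit <- catalog$substrate[catalog$family == key]
  if (!length(hit)) {
    base <- roll_up_family(key)
    if (base != key) {
      # subfamily asked for, fall back to family-level entries
      hit <- catalog$substrate[catalog$family == base]
    } else {
      # family asked for, aggregate its subfamily entries
      hit <- catalog$substrate[roll_up_family(catalog$family) == key]
    }
  }
  intersect(.substrates, unique(hit))
}

#' Families mapped to more than one substrate
#'
#' Returns the catalog keys (at the resolution stored in the catalog, i.e.
#' subfamilies are distinct entries) whose substrate set has two or more
#' members. Subfamilies of the same family typically have narrower, single
#' substrate specificities, so multifunctionality is a property of the stored
#' (sub-)family key rather than of the rolled-up family.
#'
#' @param catalog A `cazy_catalog`.
#' @return Character vector of family labels, sorted canonically (by class
#'   GH < CE < PL < AA < FAE, then family and subfamily number).
#' @examples
#' multifunctional_families(load_catalog())
#' @export
multifunctional_families <- function(catalog) {
  ns <- tapply(catalog$substrate, catalog$family,
               function(s) length(unique(s)))
  fams <- names(ns)[ns >= 2L]
  sort_family_keys(fams)
}

# canonical ordering: class order as declared, then numeric family/subfamily
sort_family_keys <- function(labels) {
  if (!length(labels)) return(character())
  k <- parse_family_key(labels)
  ord <- order(match(k$class, .parse_classes),
               ifelse(is.na(k$family), -1L, k$family),
               ifelse(is.na(k$subfamily), -1L, k$subfamily))
  labels[ord]
}

#' Families acting on a substrate
#'
#' Inverse lookup of [substrates_of()]: all catalog (sub-)family keys mapped
#' to the given polysaccharide.
#'
#' @param catalog A `cazy_catalog`.
#' @param substrate One of the seven substrate names.
#' @return Character vector of family labels, sorted canonically.
#' @examples
#' families_for_substrate(load_catalog(), "inulin")
#' @export
families_for_substrate <- function(catalog, substrate) {
  stopifnot(length(substrate) == 1L)
  if (!substrate %in% .substrates)
    stop("unknown substrate '", substrate, "' (allowed: ",
         paste(.substrates, collapse = ", "), ")")
  sort_family_keys(unique(catalog$family[catalog$substrate == substrate]))
}

#' Count distinct families per enzyme class
#'
#' Rolls subfamilies up to their parent family (GH5_4, GH5_7 and GH5_16 all
#' count as GH5; AA3_1 as AA3) and tallies distinct families per enzyme class.
#'
#' @param catalog A `cazy_catalog`.
#' @return Named integer vector over the classes present (GH, CE, PL, AA, FAE).
#' @examples
#' family_class_counts(load_catalog())
#' @export
family_class_counts <- function(catalog) {
  fams <- unique(roll_up_family(catalog$family))
  cls <- parse_family_key(fams)$class
  tab <- table(factor(cls, levels = .cazy_classes))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
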