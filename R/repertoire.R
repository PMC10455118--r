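# Gene-level CAZy annotations -> per-species family counts, substrate totals,
# uniqueness reports, and merged ortholog sets.

#' Read a gene annotation table
#'
#' TSV with columns `species`, `gene_id`, `family`. Family labels are
#' validated and canonicalised; duplicate (species, gene_id) pairs are an
#' error.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `species`, `gene_id`, `family`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  req <- c("species", "gene_id", "family")
  if (!all(req %in% names(df)))
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  validate_annotations(df[, req])
}

validate_annotations <- function(annotations) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  key <- paste(annotations$species, annotations$gene_id)
  if (anyDuplicated(key))
    stop("duplicate (species, gene_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (nrow(annotations))
    annotations$family <- format(parse_family_key(annotations$family))
  annotations
}

#' Count genes per species and CAZy family
#'
#' Tallies annotated genes into a species x family count matrix. Counts are
#' kept at the (sub-)family resolution of the annotations after label
#' canonicalisation; aggregate views (substrate totals, class counts) roll
#' subfamilies up downstream. When a catalog is supplied, families absent
#' from it are tallied in a separate `off_catalog` matrix rather than
#' silently dropped.
#'
#' @param annotations Data frame with columns `species`, `gene_id`, `family`.
#' @param catalog Optional `cazy_catalog` used to split off-catalog families.
#' @return A list of class `repertoire_matrix` with components `counts`
#'   (integer matrix, species rows x family columns) and `off_catalog`
#'   (same shape over off-catalog families, possibly 0 columns).
#' @examples
#' ann <- data.frame(species = "sp", gene_id = c("g1", "g2"),
#'                   family = c("GH6", "GH6"))
#' count_families(ann)$counts
#' @export
count_families <- function(annotations, catalog = NULL) {
  annotations <- validate_annotations(annotations)
  species <- sort(unique(annotations$species))
  fams <- sort_family_keys(unique(annotations$family))
  counts <- matrix(0L, length(species), length(fams),
                   dimnames = list(species, fams))
  if (nrow(annotations)) {
    tab <- table(factor(annotations$species, levels = species),
                 factor(annotations$family, levels = fams))
    counts[] <- as.integer(tab)
  }
  off <- counts[, 0, drop = FALSE]
  if (!is.null(catalog)) {
    # a (sub-)family is on-catalog if it, its parent family, or one of its
    # subfamily refinements has a catalog entry (mirrors substrates_of fallback)
    on <- vapply(fams, function(f) length(substrates_of(catalog, f)) > 0,
                 logical(1))
    off <- counts[, !on, drop = FALSE]
    counts <- counts[, on, drop = FALSE]
  }
  structure(list(counts = counts, off_catalog = off),
            class = "repertoire_matrix")
}

#' @export
print.repertoire_matrix <- function(x, ...) {
  cat("CAZy repertoire: ", nrow(x$counts), " species x ", ncol(x$counts),
      " families (", sum(x$counts), " genes",
      if (ncol(x$off_catalog)) paste0("; ", sum(x$off_catalog),
                                      " genes in off-catalog families"),
      ")\n", sep = "")
  invisible(x)
}

#' Per-substrate gene totals
#'
#' Sums repertoire counts over the families mapped to each polysaccharide.
#' Genes of a multifunctional family contribute once to each substrate the
#' family is mapped to (counts are not fractionally split), so substrate
#' columns are not additive across substrates by design.
#'
#' @param repertoire A `repertoire_matrix` from [count_families()].
#' @param catalog A `cazy_catalog`.
#' @return Integer matrix, species rows x substrate columns (the full
#'   seven-substrate vocabulary).
#' @export
substrate_totals <- function(repertoire, catalog) {
  counts <- repertoire$counts
  subs <- substrate_vocabulary()
  out <- matrix(0L, nrow(counts), length(subs),
                dimnames = list(rownames(counts), subs))
  for (f in colnames(counts)) {
    for (p in substrates_of(catalog, f)) out[, p] <- out[, p] + counts[, f]
  }
  out
}

#' Report species-unique and group-exclusive families
#'
#' A family is species-unique when it is present (count >= 1) in exactly one
#' species, and group-exclusive when present in at least one species of
#' exactly one taxonomic grouping (phylum/class), with at least two carrier
#' species overall. Species-unique families are not repeated in the
#' group-exclusive list.
#'
#' @param repertoire A `repertoire_matrix`.
#' @param grouping Named character vector mapping every species (names) to a
#'   group label (e.g. phylum).
#' @return List with data frames `species_unique` (`family`, `species`) and
#'   `group_exclusive` (`family`, `group`).
#' @export
uniqueness_report <- function(repertoire, grouping) {
  counts <- repertoire$counts
  sp <- rownames(counts)
  if (!all(sp %in% names(grouping)))
    stop("grouping is missing species: ",
         paste(setdiff(sp, names(grouping)), collapse = ", "))
  su <- data.frame(family = character(), species = character(),
                   stringsAsFactors = FALSE)
  ge <- data.frame(family = character(), group = character(),
                   stringsAsFactors = FALSE)
  for (f in colnames(counts)) {
    carriers <- sp[counts[, f] >= 1L]
    if (length(carriers) == 1L) {
      su <- rbind(su, data.frame(family = f, species = carriers,
                                 stringsAsFactors = FALSE))
    } else if (length(carriers) > 1L) {
      g <- unique(grouping[carriers])
      if (length(g) == 1L)
        ge <- rbind(ge, data.frame(family = f, group = unname(g),
                                   stringsAsFactors = FALSE))
    }
  }
  list(species_unique = su, group_exclusive = ge)
}

#' Read plain-text ortholog groups
#'
#' One group per line, whitespace-separated gene identifiers (the common
#' plain-text ortholog dialect). Empty lines and `#` comments are skipped.
#'
#' @param path Path to the group file.
#' @param source Label recorded on the result.
#' @return An `ortholog_groups` object (list of character vectors with a
#'   `source` attribute).
#' @export
read_ortholog_groups <- function(path, source = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  groups <- lapply(strsplit(lines, "[[:space:]]+"), unique)
  ortholog_groups(groups, source = source)
}

#' @rdname read_ortholog_groups
#' @param groups List of character vectors of gene ids.
#' @export
ortholog_groups <- function(groups, source = "user") {
  groups <- lapply(groups, as.character)
  all <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all))
    stop("gene(s) in more than one group: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  structure(groups, class = "ortholog_groups", source = source)
}

#' Merge two ortholog group sets by transitive closure
#'
#' Two genes end up in the same merged group whenever they are co-grouped in
#' either input: the merged groups are the connected components of the graph
#' whose edges join genes sharing a group in set `a` or in set `b`. Singleton
#' genes stay singleton groups. The merge is commutative, associative and
#' idempotent.
#'
#' @param a,b `ortholog_groups` objects.
#' @return An `ortholog_groups` object covering every input gene exactly once,
#'   groups and members sorted for determinism.
#' @examples
#' merge_ortholog_groups(ortholog_groups(list(c("x", "y"))),
#'                       ortholog_groups(list(c("y", "z"))))
#' @export
merge_ortholog_groups <- function(a, b) {
  stopifnot(inherits(a, "ortholog_groups"), inherits(b, "ortholog_groups"))
  genes <- unique(c(unlist(a, use.names = FALSE), unlist(b, use.names = FALSE)))
  if (!length(genes)) return(ortholog_groups(list(), source = "merged"))
  parent <- seq_along(genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  idx <- function(g) match(g, genes)
  for (grp in c(unclass(a), unclass(b))) {
    ii <- idx(grp)
    if (length(ii) > 1L) for (k in seq_along(ii)[-1L]) union_(ii[1L], ii[k])
  }
  roots <- vapply(seq_along(genes), find, integer(1))
  comps <- split(genes, roots)
  comps <- lapply(unname(comps), sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  ortholog_groups(comps, source = "merged")
}

#' @export
print.ortholog_groups <- function(x, ...) {
  cat("ortholog groups (", attr(x, "source"), "): ", length(x), " groups, ",
      length(unlist(x, use.names = FALSE)), " genes\n", sep = "")
  invisible(x)
}

#' Write repertoire outputs as TSV
#'
#' @param x Matrix or data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else df <- x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
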