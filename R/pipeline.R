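# End-to-end orchestration: one configuration in, a bundle of TSV reports out.

#' Run the full comparative CAZyme analysis pipeline
#'
#' Executes the stages in order for each configured species — annotation
#' reading, repertoire counting, substrate totals, expression reading,
#' replicate collapse, low-expression filtering, per-substrate expression
#' summaries, SSG classification and cross-tabulation — then merges species
#' and, if growth data are configured, computes repertoire-growth concordance
#' and discordance reports. All stage outputs are written as TSV under
#' `out_dir` together with a JSON run manifest (thresholds, input checksums,
#' per-stage gene counts). Outputs are deterministic given inputs.
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   `species`: named list, one entry per species, each with `annotations`,
#'   `expression`, `metadata` paths; optional `catalog` path (default:
#'   packaged catalog); optional `growth` and `substrate_map` paths;
#'   `ssi_threshold`, `fpkm_threshold` (defaults 0.7 and 10); `out_dir`.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the in-memory results (`repertoire`,
#'   `totals`, `summaries`, `records`, `crosstabs`, `concordance`,
#'   `discordant`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ssi_thr <- config$ssi_threshold %||% 0.7
  fpkm_thr <- config$fpkm_threshold %||% 10
  catalog <- load_catalog(config$catalog)
  if (is.null(config$species) || !length(config$species))
    stop("config lists no species")

  inputs <- character()
  counts_ledger <- list()
  all_ann <- list()
  records <- list()
  crosstabs <- list()
  summaries <- list()

  for (sp in names(config$species)) {
    spc <- config$species[[sp]]
    for (f in unlist(spc[c("annotations", "expression", "metadata")])) {
      if (!is.null(f) && !file.exists(f))
        stop("stage '", sp, "': input file not found: ", f)
    }
    inputs <- c(inputs, unlist(spc))
    ann <- read_annotations(spc$annotations)
    all_ann[[sp]] <- ann
    em <- read_expression(spc$expression, spc$metadata)
    cm <- collapse_replicates(em)
    n_in <- nrow(cm)
    cmf <- filter_low_expression(cm, fpkm_thr)
    counts_ledger[[sp]] <- list(genes_in = n_in, genes_kept = nrow(cmf),
                                genes_filtered = n_in - nrow(cmf))
    summaries[[sp]] <- group_expression_summary(cmf, ann, catalog)
    cfg <- specificity_config(ssi_threshold = ssi_thr,
                              fpkm_threshold = fpkm_thr)
    rec <- classify_ssg(cmf, cfg)
    records[[sp]] <- rec
    crosstabs[[sp]] <- ssg_crosstab(rec, ann, catalog)
    write_tsv_matrix(as.data.frame(rec), file.path(out_dir,
                                                   paste0(sp, "_ssg.tsv")))
    write_tsv_matrix(crosstabs[[sp]],
                     file.path(out_dir, paste0(sp, "_crosstab.tsv")))
    write_tsv_matrix(summaries[[sp]],
                     file.path(out_dir, paste0(sp, "_expression_summary.tsv")))
  }

  ann_merged <- do.call(rbind, c(all_ann, list(make.row.names = FALSE)))
  rep_mat <- count_families(ann_merged, catalog)
  totals <- substrate_totals(rep_mat, catalog)
  write_tsv_matrix(t(rep_mat$counts), file.path(out_dir, "repertoire.tsv"))
  write_tsv_matrix(totals, file.path(out_dir, "substrate_totals.tsv"))

  concordance <- discordant <- NULL
  if (!is.null(config$growth)) {
    if (!file.exists(config$growth))
      stop("stage 'concordance': input file not found: ", config$growth)
    growth <- read_growth(config$growth)
    gsub_ <- map_growth_substrates(growth, config$substrate_map)
    concordance <- rank_concordance(totals, gsub_)
    discordant <- flag_discordant(totals, gsub_)
    write_tsv_matrix(concordance, file.path(out_dir, "concordance.tsv"))
    write_tsv_matrix(discordant, file.path(out_dir, "discordance.tsv"))
  }

  manifest <- list(
    package = "cazyspec",
    version = as.character(utils::packageVersion("cazyspec")),
    thresholds = list(ssi = ssi_thr, fpkm = fpkm_thr),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    gene_ledger = counts_ledger)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(repertoire = rep_mat, totals = totals, summaries = summaries,
                 records = records, crosstabs = crosstabs,
                 concordance = concordance, discordant = discordant,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
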