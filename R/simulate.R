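# Synthetic FPKM matrices with planted sugar-specific genes.
#
# Each gene g draws an expression scale e_g ~ lognormal(mu, sigma). A
# "specific" gene has pre-noise mean e_g in its (randomly drawn) inducing
# condition and lambda * e_g in every other condition, so its noiseless
# specificity index is exactly 1 - lambda. A "background" gene has mean e_g
# everywhere (noiseless index 0). A "silent" gene is uniform with a scale
# below the FPKM filter, exercising the low-expression path. Every sample
# value is multiplied by independent lognormal(0, sigma_n) noise.

#' Simulation configuration
#'
#' @param n_genes Number of genes (default 1000).
#' @param conditions Condition names (default the nine monosaccharides of
#'   [monosaccharide_conditions()]).
#' @param n_replicates Replicates per condition (default 3).
#' @param frac_specific Fraction of genes planted as sugar-specific
#'   (default 0.10).
#' @param frac_silent Fraction of genes scaled below the expression filter
#'   (default 0.10). `frac_specific + frac_silent` must be <= 1.
#' @param leakage Leakage lambda in \[0, 1): non-inducing expression of a
#'   specific gene as a fraction of its inducing-condition expression
#'   (default 0.1).
#' @param base_log_mean,base_log_sd Meanlog/sdlog of the lognormal gene
#'   expression scale, FPKM units (defaults `log(100)` and 1).
#' @param noise_log_sd Sdlog of the multiplicative per-sample lognormal noise
#'   (default 0.2; 0 = noiseless).
#' @param silent_ceiling Upper bound on silent-gene pre-noise means; silent
#'   scales are drawn uniformly on (0.05, 0.95) times this (default 10, the
#'   conventional FPKM filter).
#' @param seed Integer seed driving all draws (default 1).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000L,
                              conditions = monosaccharide_conditions(),
                              n_replicates = 3L,
                              frac_specific = 0.10,
                              frac_silent = 0.10,
                              leakage = 0.1,
                              base_log_mean = log(100),
                              base_log_sd = 1,
                              noise_log_sd = 0.2,
                              silent_ceiling = 10,
                              seed = 1L) {
  stopifnot(n_genes >= 1, length(conditions) >= 2, n_replicates >= 1,
            frac_specific >= 0, frac_silent >= 0,
            frac_specific + frac_silent <= 1,
            leakage >= 0, leakage < 1,
            base_log_sd >= 0, noise_log_sd >= 0, silent_ceiling > 0)
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 frac_specific = frac_specific, frac_silent = frac_silent,
                 leakage = leakage, base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd, noise_log_sd = noise_log_sd,
                 silent_ceiling = silent_ceiling, seed = as.integer(seed)),
            class = "simulation_config")
}

# one generator drives everything; sub-streams are derived deterministically
with_sim_seed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Simulate an expression matrix with planted sugar-specific genes
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (an `expression_matrix` with replicate
#'   metadata) and `truth` (data frame `gene_id`, `label` in
#'   `{specific, background, silent}`, `true_condition` (`NA` unless
#'   specific), `true_ssi_noiseless`).
#' @examples
#' sim <- simulate_expression(simulation_config(n_genes = 20, seed = 42))
#' table(sim$truth$label)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  conds <- config$conditions
  k <- length(conds)
  with_sim_seed(config$seed, 0L, {
    n_spec <- round(config$frac_specific * n)
    n_sil <- round(config$frac_silent * n)
    label <- rep("background", n)
    if (n_spec > 0) label[seq_len(n_spec)] <- "specific"
    if (n_sil > 0) label[n_spec + seq_len(n_sil)] <- "silent"
    gene_id <- sprintf("gene%04d", seq_len(n))
    # non-silent scales: lognormal truncated above the silent ceiling, so a
    # planted specific or background gene is by construction detectable under
    # the default expression filter and the truth labels partition cleanly
    p0 <- stats::plnorm(config$silent_ceiling, config$base_log_mean,
                        config$base_log_sd)
    scale <- stats::qlnorm(stats::runif(n, p0, 1), config$base_log_mean,
                           config$base_log_sd)
    silent_scale <- stats::runif(n, 0.05, 0.95) * config$silent_ceiling
    scale[label == "silent"] <- silent_scale[label == "silent"]
    true_cond <- rep(NA_character_, n)
    true_cond[label == "specific"] <- sample(conds, n_spec, replace = TRUE)
    # pre-noise per-condition means
    mu <- matrix(rep(scale, k), n, k, dimnames = list(gene_id, conds))
    for (i in which(label == "specific")) {
      mu[i, ] <- config$leakage * scale[i]
      mu[i, true_cond[i]] <- scale[i]
    }
    meta <- data.frame(
      sample_id = paste0(rep(conds, each = config$n_replicates), "_r",
                         rep(seq_len(config$n_replicates), k)),
      condition = rep(conds, each = config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), k),
      stringsAsFactors = FALSE)
    vals <- mu[, meta$condition, drop = FALSE]
    colnames(vals) <- meta$sample_id
    if (config$noise_log_sd > 0)
      vals <- vals * matrix(stats::rlnorm(n * nrow(meta), 0,
                                          config$noise_log_sd),
                            n, nrow(meta))
    truth <- data.frame(
      gene_id = gene_id, label = label, true_condition = true_cond,
      true_ssi_noiseless = ifelse(label == "specific", 1 - config$leakage, 0),
      stringsAsFactors = FALSE)
    list(expression = expression_matrix(vals, meta, conditions = conds),
         truth = truth)
  })
}

#' Simulate gene annotations over a catalog
#'
#' Assigns each synthetic gene a CAZy (sub-)family drawn uniformly from the
#' distinct family keys of the catalog.
#'
#' @param config A [simulation_config()].
#' @param catalog A `cazy_catalog`.
#' @param species Species label recorded in the annotations.
#' @return Annotation data frame `species`, `gene_id`, `family`.
#' @export
simulate_annotations <- function(config, catalog, species = "synthetic") {
  stopifnot(inherits(config, "simulation_config"), nrow(catalog) > 0)
  fams <- sort_family_keys(unique(catalog$family))
  with_sim_seed(config$seed, 1L, {
    data.frame(species = species,
               gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
               family = sample(fams, config$n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Recovery metrics of the SSG classification against planted truth
#'
#' Confusion-matrix metrics of the sugar-specific-gene calls against the
#' simulation's planted labels: genes planted `specific` are the positives;
#' `background` and `silent` genes the negatives.
#'
#' @param records An `ssg_classification` (or data frame with `gene_id`,
#'   `is_ssg`, `inducing_condition`).
#' @param truth Truth table from [simulate_expression()].
#' @return List with `sensitivity`, `specificity`, `false_discovery_rate`
#'   (0 when nothing is called), and `inducing_condition_accuracy` (fraction
#'   of true-positive calls whose inducing condition matches the planted one;
#'   `NaN` when there are no true positives).
#' @export
recovery_metrics <- function(records, truth) {
  if (!setequal(records$gene_id, truth$gene_id))
    stop("record and truth gene sets differ")
  truth <- truth[match(records$gene_id, truth$gene_id), , drop = FALSE]
  pos <- truth$label == "specific"
  called <- records$is_ssg
  tp <- sum(pos & called)
  fp <- sum(!pos & called)
  tn <- sum(!pos & !called)
  fn <- sum(pos & !called)
  acc <- if (tp > 0) {
    idx <- pos & called
    mean(records$inducing_condition[idx] == truth$true_condition[idx])
  } else NaN
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
       false_discovery_rate = if (tp + fp > 0) fp / (tp + fp) else 0,
       inducing_condition_accuracy = acc)
}

#' Write a simulated bundle to TSV files
#'
#' Writes the standard expression, metadata, annotation and truth tables a
#' pipeline run consumes.
#'
#' @param sim Result of [simulate_expression()].
#' @param annotations Result of [simulate_annotations()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_simulation <- function(sim, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "samples.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  em <- sim$expression
  write_tsv_matrix(data.frame(gene_id = rownames(em$values),
                              as.data.frame(em$values, check.names = FALSE),
                              check.names = FALSE, stringsAsFactors = FALSE),
                   paths["expression"])
  write_tsv_matrix(em$meta, paths["metadata"])
  write_tsv_matrix(annotations, paths["annotations"])
  write_tsv_matrix(sim$truth, paths["truth"])
  invisible(paths)
}
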