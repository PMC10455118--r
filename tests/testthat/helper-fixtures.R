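# Shared fixture builders for the test suite. Everything is generated in code.

# small condition matrix with named genes/conditions
make_cm <- function(values, conditions = NULL) {
  m <- matrix(unlist(values), nrow = length(values), byrow = TRUE)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- conditions %||% paste0("cond", seq_len(ncol(m)))
  condition_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation table over arbitrary families
make_ann <- function(families, species = "sp1") {
  data.frame(species = rep(species, length.out = length(families)),
             gene_id = sprintf("g%d", seq_along(families)),
             family = families, stringsAsFactors = FALSE)
}

# direct evaluation of the specificity-index formula, written independently
# of the package implementation: explicit loop over conditions
ssi_oracle <- function(x) {
  n <- length(x)
  xhat <- numeric(n)
  mx <- 0
  for (v in x) if (v > mx) mx <- v
  for (i in seq_len(n)) xhat[i] <- x[i] / mx
  total <- 0
  for (i in seq_len(n)) total <- total + (1 - xhat[i])
  total / (n - 1)
}

# write a small expression matrix + metadata pair to tempfiles; the tempdir
# lives until the caller's frame exits
write_expr_fixture <- function(values, meta,
                               dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  sp <- file.path(dir, "meta.tsv")
  df <- data.frame(gene_id = rownames(values),
                   as.data.frame(values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, meta = sp)
}
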