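test_that("expression reading validates structure and reorders samples", {
  vals <- matrix(runif(27, 0, 50), 3, 9,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:9)))
  meta <- data.frame(sample_id = paste0("s", 9:1),
                     condition = rev(monosaccharide_conditions()),
                     replicate = 1L)
  fx <- write_expr_fixture(vals, meta)
  em <- read_expression(fx$matrix, fx$meta)
  expect_equal(dim(em$values), c(3L, 9L))
  expect_equal(colnames(em$values), meta$sample_id)  # metadata order
  expect_equal(em$values["g2", "s5"], vals["g2", "s5"])
})

test_that("reading errors name the offending column, value, or gene", {
  vals <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample_id = "s1", condition = "D-glucose",
                     replicate = 1L)
  fx <- write_expr_fixture(vals, meta)
  expect_error(read_expression(fx$matrix, fx$meta), "s2")

  meta2 <- data.frame(sample_id = c("s1", "s2"),
                      condition = c("D-glucose", "D-xylose"),
                      replicate = 1L)
  vals2 <- vals; vals2["g2", "s1"] <- -1
  fx2 <- write_expr_fixture(vals2, meta2)
  expect_error(read_expression(fx2$matrix, fx2$meta), "g2.*s1")

  vals3 <- vals; rownames(vals3) <- c("g1", "g1")
  fx3 <- write_expr_fixture(vals3, meta2)
  expect_error(read_expression(fx3$matrix, fx3$meta), "duplicate gene")

  expect_error(expression_matrix(vals, meta2, conditions = c("a", "b")),
               "vocabulary")
})

test_that("replicate collapse takes per-condition arithmetic means", {
  vals <- matrix(c(4, 6, 10, 1, 3, 20), 1, 6,
                 dimnames = list("g1", paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     condition = rep(c("c1", "c2", "c3"), each = 2),
                     replicate = rep(1:2, 3))
  cm <- collapse_replicates(expression_matrix(vals, meta))
  expect_equal(unclass(cm)["g1", ], c(c1 = 5, c2 = 5.5, c3 = 11.5))
  # single replicate: identity
  meta1 <- meta[meta$replicate == 1L, ]
  cm1 <- collapse_replicates(expression_matrix(
    vals[, meta1$sample_id, drop = FALSE], meta1))
  expect_equal(unname(unclass(cm1)["g1", ]), unname(vals[1, c(1, 3, 5)]))
})

test_that("replicate collapse matches brute-force means on random matrices", {
  set.seed(404)
  conds <- c("c1", "c2", "c3", "c4")
  for (rep in 1:10) {
    nr <- sample(2:4, 1)
    meta <- data.frame(
      sample_id = paste0("s", seq_len(nr * length(conds))),
      condition = rep(conds, each = nr), replicate = rep(seq_len(nr),
                                                         length(conds)))
    vals <- matrix(rexp(6 * nrow(meta), 0.05), 6, nrow(meta),
                   dimnames = list(paste0("g", 1:6), meta$sample_id))
    cm <- collapse_replicates(expression_matrix(vals, meta))
    for (g in rownames(vals)) {
      for (cc in conds) {
        brute <- mean(vals[g, meta$sample_id[meta$condition == cc]])
        expect_equal(unclass(cm)[g, cc], brute)
      }
    }
  }
  # collapse commutes with gene subsetting
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     condition = rep(c("c1", "c2"), each = 4),
                     replicate = rep(1:4, 2))
  vals <- matrix(runif(40), 5, 8,
                 dimnames = list(paste0("g", 1:5), meta$sample_id))
  full <- collapse_replicates(expression_matrix(vals, meta))
  sub <- collapse_replicates(expression_matrix(vals[c("g2", "g4"), ], meta))
  expect_equal(unclass(full)[c("g2", "g4"), ], unclass(sub)[, ])
})

test_that("low-expression filter applies the strict less-than rule", {
  cm <- make_cm(list(c(9.9, 3, 0), c(10, 0, 0), c(50, 1, 2), c(0, 0, 0)))
  kept <- filter_low_expression(cm, 10)
  expect_equal(rownames(kept), c("g2", "g3"))   # max 9.9 removed, max 10 kept
  expect_equal(rownames(filter_low_expression(cm, 0)), rownames(cm))
  # idempotent
  expect_equal(unclass(filter_low_expression(kept, 10)), unclass(kept))
  # monotone: higher threshold retains a subset
  set.seed(405)
  big <- condition_matrix(matrix(rexp(300, 0.1), 50, 6,
                                 dimnames = list(paste0("g", 1:50), NULL)))
  for (thr in c(2, 5, 10, 20)) {
    lo <- rownames(filter_low_expression(big, thr))
    hi <- rownames(filter_low_expression(big, thr * 2))
    expect_true(all(hi %in% lo))
  }
})

test_that("group summaries compute quartiles, whiskers and IQR outliers", {
  cat_ <- load_catalog()
  ann <- data.frame(species = "sp", gene_id = paste0("g", 1:5),
                    family = "GH11")  # xylan only
  m <- matrix(rep(c(1, 2, 3, 4, 100), 2), 5, 2,
              dimnames = list(paste0("g", 1:5), c("c1", "c2")))
  cm2 <- condition_matrix(m)
  s <- group_expression_summary(cm2, ann, cat_)
  xl <- s[s$substrate == "xylan" & s$condition == "c1", ]
  expect_equal(xl$n_genes, 5L)
  expect_equal(xl$median, 3)
  expect_equal(xl$q1, 2)
  expect_equal(xl$q3, 4)
  expect_equal(xl$whisker_lo, 1)
  expect_equal(xl$whisker_hi, 4)
  expect_equal(xl$outlier_ids, "g5")
  # substrates with no genes give empty entries, not errors
  pc <- s[s$substrate == "pectin" & s$condition == "c1", ]
  expect_equal(pc$n_genes, 0L)
  expect_true(is.na(pc$median))
  # single-gene group: median is its value, no outliers
  s1 <- group_expression_summary(cm2, ann[1, ], cat_)
  x1 <- s1[s1$substrate == "xylan" & s1$condition == "c1", ]
  expect_equal(x1$median, 1)
  expect_equal(x1$outlier_ids, "")
})

test_that("group summaries put multifunctional genes in every mapped group
           and ignore gene order", {
  cat_ <- load_catalog()
  ann <- data.frame(species = "sp", gene_id = c("g1", "g2"),
                    family = c("GH12", "GH11"))
  cm <- make_cm(list(c(5, 7), c(2, 9)))
  s <- group_expression_summary(cm, ann, cat_)
  expect_equal(s$n_genes[s$substrate == "cellulose" & s$condition == "cond1"],
               1L)
  expect_equal(s$n_genes[s$substrate == "xyloglucan" & s$condition == "cond1"],
               1L)
  expect_equal(s$n_genes[s$substrate == "xylan" & s$condition == "cond1"], 1L)
  # row order invariance
  cm_rev <- condition_matrix(unclass(cm)[2:1, ])
  expect_equal(group_expression_summary(cm_rev, ann, cat_), s)
})
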