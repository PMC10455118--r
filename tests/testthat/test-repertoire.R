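test_that("count_families tallies genes per species and family", {
  ann <- data.frame(species = c("A", "A", "A", "B"),
                    gene_id = c("g1", "g2", "g3", "g1"),
                    family = c("GH6", "GH6", "GH7", "GH6"),
                    stringsAsFactors = FALSE)
  rm_ <- count_families(ann)
  expect_equal(rm_$counts["A", "GH6"], 2L)
  expect_equal(rm_$counts["A", "GH7"], 1L)
  expect_equal(rm_$counts["B", "GH6"], 1L)
  expect_equal(sum(rm_$counts["A", ]), 3L)
  expect_equal(sum(rm_$counts), nrow(ann))
})

test_that("count_families handles empty input and rejects duplicates", {
  empty <- data.frame(species = character(), gene_id = character(),
                      family = character(), stringsAsFactors = FALSE)
  expect_equal(sum(count_families(empty)$counts), 0L)
  dup <- make_ann(c("GH6", "GH7"))
  dup$gene_id <- c("g1", "g1")
  expect_error(count_families(dup), "duplicate")
})

test_that("count_families matches brute-force tallying on random fixtures", {
  set.seed(401)
  fams <- c("GH3", "GH5_7", "GH11", "CE8", "PL1", "AA9", "FAE", "GH28")
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    ann <- data.frame(species = sample(c("s1", "s2", "s3"), n, replace = TRUE),
                      gene_id = paste0("g", seq_len(n)),
                      family = sample(fams, n, replace = TRUE),
                      stringsAsFactors = FALSE)
    rm_ <- count_families(ann)
    for (sp in rownames(rm_$counts)) {
      for (f in colnames(rm_$counts)) {
        brute <- 0L
        for (i in seq_len(n)) {
          if (ann$species[i] == sp && ann$family[i] == f) brute <- brute + 1L
        }
        expect_identical(rm_$counts[sp, f], brute)
      }
    }
  }
})

test_that("off-catalog families are reported separately, not dropped", {
  cat_ <- load_catalog()
  ann <- make_ann(c("GH6", "GH9999", "GT2"))
  rm_ <- count_families(ann, cat_)
  expect_equal(colnames(rm_$counts), "GH6")
  expect_setequal(colnames(rm_$off_catalog), c("GH9999", "GT2"))
  expect_equal(sum(rm_$counts) + sum(rm_$off_catalog), 3L)
})

test_that("substrate totals credit multifunctional families to each substrate", {
  cat_ <- load_catalog()
  # only GH32 genes: all 5 go to inulin, nothing elsewhere
  rm_ <- count_families(make_ann(rep("GH32", 5)), cat_)
  tot <- substrate_totals(rm_, cat_)
  expect_equal(tot[1, "inulin"], 5L)
  expect_equal(sum(tot), 5L)
  # one GH12 gene counts under both cellulose and xyloglucan
  tot2 <- substrate_totals(count_families(make_ann("GH12"), cat_), cat_)
  expect_equal(tot2[1, "cellulose"], 1L)
  expect_equal(tot2[1, "xyloglucan"], 1L)
  expect_equal(sum(tot2), 2L)
  # empty repertoire -> zero table
  empty <- count_families(make_ann(character()), cat_)
  expect_equal(sum(substrate_totals(empty, cat_)), 0L)
})

test_that("substrate totals are additive over annotation sets", {
  cat_ <- load_catalog()
  set.seed(402)
  fams <- unique(cat_$family)
  for (rep in 1:10) {
    a1 <- data.frame(species = "s1", gene_id = paste0("a", 1:15),
                     family = sample(fams, 15, replace = TRUE))
    a2 <- data.frame(species = "s1", gene_id = paste0("b", 1:10),
                     family = sample(fams, 10, replace = TRUE))
    t1 <- substrate_totals(count_families(a1, cat_), cat_)
    t2 <- substrate_totals(count_families(a2, cat_), cat_)
    t12 <- substrate_totals(count_families(rbind(a1, a2), cat_), cat_)
    expect_equal(t12["s1", ], t1["s1", ] + t2["s1", ])
  }
})

test_that("uniqueness report separates species-unique from group-exclusive", {
  ann <- rbind(
    make_ann("GH44", species = "D.squalens"),              # unique carrier
    data.frame(species = c("A.niger", "A.nidulans"),
               gene_id = c("x1", "x2"), family = "GH62"),  # one class only
    data.frame(species = c("A.niger", "A.nidulans", "D.squalens"),
               gene_id = c("y1", "y2", "y3"), family = "GH3"))
  grouping <- c(A.niger = "Ascomycota", A.nidulans = "Ascomycota",
                D.squalens = "Basidiomycota")
  rep_ <- uniqueness_report(count_families(ann), grouping)
  expect_equal(rep_$species_unique$family, "GH44")
  expect_equal(rep_$species_unique$species, "D.squalens")
  expect_equal(rep_$group_exclusive$family, "GH62")
  expect_equal(rep_$group_exclusive$group, "Ascomycota")
  expect_false("GH3" %in% c(rep_$species_unique$family,
                            rep_$group_exclusive$family))
})

test_that("ortholog merge joins co-grouped genes transitively", {
  a <- ortholog_groups(list(c("x", "y")))
  b <- ortholog_groups(list(c("y", "z")))
  m <- merge_ortholog_groups(a, b)
  expect_length(m, 1L)
  expect_setequal(m[[1]], c("x", "y", "z"))
  # idempotence and disjoint-universe concatenation
  expect_equal(unclass(merge_ortholog_groups(a, a))[[1]], c("x", "y"))
  d <- merge_ortholog_groups(ortholog_groups(list(c("p", "q"))),
                             ortholog_groups(list(c("r", "s"))))
  expect_length(d, 2L)
})

test_that("ortholog merge matches graph components; commutative and associative", {
  skip_if_not_installed("igraph")
  set.seed(403)
  random_groups <- function(genes) {
    pool <- sample(genes, sample(3:length(genes), 1))
    sizes <- diff(sort(unique(c(0, sample(length(pool), 3), length(pool)))))
    sizes <- sizes[sizes > 0]
    ortholog_groups(split(pool, rep(seq_along(sizes), sizes)))
  }
  oracle_components <- function(a, b) {
    genes <- unique(c(unlist(a), unlist(b)))
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
    for (grp in c(unclass(a), unclass(b))) {
      if (length(grp) > 1) {
        for (k in 2:length(grp)) g <- g + igraph::edges(c(grp[1], grp[k]))
      }
    }
    comp <- igraph::components(g)$membership
    unname(lapply(split(names(comp), comp), sort))
  }
  canon <- function(gs)
    sort(vapply(gs, function(g) paste(sort(g), collapse = "|"), character(1)))
  genes <- paste0("gene", 1:12)
  for (rep in 1:100) {
    a <- random_groups(genes)
    b <- random_groups(genes)
    m <- merge_ortholog_groups(a, b)
    expect_equal(canon(unclass(m)), canon(oracle_components(a, b)))
    # commutativity
    m2 <- merge_ortholog_groups(b, a)
    expect_equal(unclass(m), unclass(m2))
    # idempotence of the merged set
    expect_equal(unclass(merge_ortholog_groups(m, m)), unclass(m))
  }
  # associativity on triples
  for (rep in 1:20) {
    a <- random_groups(genes); b <- random_groups(genes)
    c_ <- random_groups(genes)
    lhs <- merge_ortholog_groups(merge_ortholog_groups(a, b), c_)
    rhs <- merge_ortholog_groups(a, merge_ortholog_groups(b, c_))
    expect_equal(unclass(lhs), unclass(rhs))
  }
})

test_that("ortholog group files read the one-group-per-line dialect", {
  p <- withr::local_tempfile(lines = c("# comment", "g1 g2  g3", "", "g4"))
  og <- read_ortholog_groups(p)
  expect_length(og, 2L)
  expect_equal(og[[1]], c("g1", "g2", "g3"))
  expect_equal(og[[2]], "g4")
  expect_error(ortholog_groups(list(c("a", "b"), c("b", "c"))),
               "more than one group")
})
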