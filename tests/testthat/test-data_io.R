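write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("plain dialect: zero matrix, validation errors, ordering", {
  p <- write_tsv_fixture(c("gene_id\tg1\tg2\tg3",
                           "geneA\t0\t0\t0",
                           "geneB\t0\t0\t0"))
  out <- read_presence_matrix(p, dialect = "plain")
  expect_equal(out$Y, matrix(0L, 2, 3,
                             dimnames = list(c("geneA", "geneB"),
                                             c("g1", "g2", "g3"))))
  expect_equal(out$gene_ids, c("geneA", "geneB"))

  bad <- write_tsv_fixture(c("gene_id\tg1\tg2",
                             "geneA\t0\t2"))
  expect_error(read_presence_matrix(bad), "geneA.*g2|g2.*geneA")

  dup <- write_tsv_fixture(c("gene_id\tg1\tg2",
                             "geneA\t0\t1",
                             "geneA\t1\t1"))
  expect_error(read_presence_matrix(dup), "duplicated gene")
  expect_error(read_presence_matrix(tempfile()), "not found")
})

test_that("roary dialect: non-empty cells mean presence; equivalent to binarized plain", {
  ann <- paste(rep("x", 13), collapse = ",")
  p <- write_tsv_fixture(c(
    paste0("Gene,", paste(paste0("a", 1:13), collapse = ","), ",s1,s2,s3"),
    paste0("\"grpA\",", ann, ",groupA_00123,,groupA_00125"),
    paste0("\"grpB\",", ann, ",,groupB_00200,")
  ), ext = ".csv")
  out <- read_presence_matrix(p, dialect = "roary", first_genome_col = 15)
  expect_equal(unname(out$Y), matrix(c(1L, 0L, 0L, 1L, 1L, 0L), 2, 3))
  expect_equal(out$genome_ids, c("s1", "s2", "s3"))

  # its binarized plain-dialect counterpart yields the identical matrix
  p2 <- write_tsv_fixture(c("gene_id\ts1\ts2\ts3",
                            "grpA\t1\t0\t1",
                            "grpB\t0\t1\t0"))
  out2 <- read_presence_matrix(p2, dialect = "plain")
  expect_equal(unname(out$Y), unname(out2$Y))
})

test_that("presence matrix round-trips through write and read", {
  withr::with_seed(10, {
    Y <- matrix(rbinom(100, 1, 0.4), 10, 10,
                dimnames = list(paste0("gene", 1:10), paste0("gn", 1:10)))
  })
  path <- tempfile(fileext = ".tsv")
  write_presence_matrix(Y, path = path)
  back <- read_presence_matrix(path)
  expect_equal(unname(back$Y), unname(Y))
  expect_equal(back$gene_ids, rownames(Y))
  expect_equal(back$genome_ids, colnames(Y))
})

test_that("metadata: categorical coding, realignment, range preservation, errors", {
  md <- write_tsv_fixture(c(
    "genome\tsite\tcoverage",
    "g2\ttongue\t26.35",
    "g1\tplaque\t1.07",
    "g3\ttongue\t5.5"
  ))
  out <- read_metadata(md, "genome", "site", "coverage",
                       genome_order = c("g1", "g2", "g3"))
  # rows realigned to the matrix order
  expect_equal(out$genome_ids, c("g1", "g2", "g3"))
  # treatment coding against the lexicographically first level (plaque)
  expect_equal(unname(out$X[, 2]), c(0, 1, 1))
  expect_match(colnames(out$X)[2], "site=tongue \\(vs plaque\\)")
  expect_equal(unname(out$X[, 1]), rep(1, 3))  # intercept
  expect_equal(range(out$M), c(1.07, 26.35))

  expect_error(read_metadata(md, "genome", "site", "coverage",
                             genome_order = c("g1", "g2", "g4")),
               "g4")
  md_na <- write_tsv_fixture(c("genome\tsite\tcoverage",
                               "g1\t\t3.2", "g2\ttongue\t4"))
  expect_error(read_metadata(md_na, "genome", "site", "coverage"),
               "missing")
  expect_error(read_metadata(md, "genome", "nope", "coverage"), "nope")
})

test_that("per-gene p-values are invariant to metadata row order", {
  # shuffling metadata rows (with realignment by genome id) must not change
  # the downstream test result
  withr::with_seed(44, {
    n <- 24
    ids <- paste0("g", 1:n)
    M <- round(runif(n, 5, 40), 3)
    x <- round(rnorm(n), 3)
    y <- rbinom(n, 1, plogis(0.5 * x))
  })
  mat <- write_tsv_fixture(c(paste(c("gene_id", ids), collapse = "\t"),
                             paste(c("geneA", y), collapse = "\t")))
  meta_fwd <- c("genome\tx\tcov", paste(ids, x, M, sep = "\t"))
  perm <- c(seq(2, n, 2), seq(1, n, 2))
  f1 <- write_tsv_fixture(meta_fwd)
  f2 <- write_tsv_fixture(meta_fwd[c(1, 1 + perm)])
  run <- function(meta_path) {
    mt <- read_presence_matrix(mat)
    md <- read_metadata(meta_path, "genome", "x", "cov",
                        genome_order = mt$genome_ids)
    lp_single_test(mt$Y[1, ], md$X, md$M[, 1],
                   lp_hypothesis(test_cols = 2, p = 2),
                   method = "asymptotic",
                   control = lp_control(delta = 0.1))$p_value
  }
  expect_equal(run(f1), run(f2), tolerance = 1e-12)
})

test_that("result tables round-trip with 12-digit precision and fixed columns", {
  tab <- data.frame(
    gene_id = "geneA", method = "happi-a",
    statistic = 3.14159265358979, p_value = 0.03, q_value = 0.03,
    converged_alt = TRUE, converged_null = TRUE,
    n_iter_alt = 16L, n_iter_null = 16L
  )
  path <- tempfile(fileext = ".tsv")
  write_results(tab, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 1)
  expect_equal(colnames(back), latentpan:::RESULT_COLUMNS)
  expect_equal(back$statistic, tab$statistic, tolerance = 1e-12)
  expect_equal(back$p_value, 0.03, tolerance = 1e-12)
  # BH with a single gene is the identity
  expect_equal(back$q_value, back$p_value)

  expect_error(write_results(tab[0, ], tempfile()), "nrow")
})

test_that("dataset container enforces its invariants", {
  Y <- matrix(c(0, 1, 1, 0), 2, 2)
  X <- cbind(1, c(0, 1))
  M <- c(5, 10)
  ds <- gene_presence_dataset(Y, X, M)
  expect_s3_class(ds, "gene_presence_dataset")
  expect_error(gene_presence_dataset(Y * 2, X, M), "0 or 1")
  expect_error(gene_presence_dataset(Y, X[1, , drop = FALSE], M),
               "genome columns")
  Yna <- Y; Yna[1] <- NA
  expect_error(gene_presence_dataset(Yna, X, M), "missing")
})
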