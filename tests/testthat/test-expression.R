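write_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mat <- c("!series comment line to be ignored",
           "gene_id\tsA\tsB\tsC\tsD",
           "g1\t1.5\t2.25\t3\t4.125",
           "g2\t5\t6\t7\t8",
           "g3\t0.5\t0.25\t0.125\t9")
  ann <- c("sample_id\toutcome\tstrata",
           "sA\t0\tERpos", "sB\t1\tERneg", "sC\t0\tERpos", "sD\t1\tERpos")
  mp <- file.path(dir, "expr.tsv"); ap <- file.path(dir, "ann.tsv")
  writeLines(mat, mp); writeLines(ann, ap)
  list(matrix = mp, annotation = ap, dir = dir)
}

test_that("reading a matrix + annotation pair yields the expected dataset", {
  fx <- write_fixture()
  ds <- read_expression(fx$matrix, fx$annotation)
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(rownames(ds$values), c("g1", "g2", "g3"))
  expect_equal(unname(outcomes(ds)), c(0L, 1L, 0L, 1L))
  expect_equal(ds$values["g1", "sD"], 4.125)
})

test_that("samples are intersected and problem inputs are load errors", {
  fx <- write_fixture()
  # annotation with an extra (5th) sample: intersection keeps the 4
  writeLines(c(readLines(fx$annotation), "sE\t1\tERpos"), fx$annotation)
  expect_warning(ds <- read_expression(fx$matrix, fx$annotation),
                 "absent from the matrix")
  expect_equal(dim(ds)[2], 4L)

  fx2 <- write_fixture()
  lines <- readLines(fx2$matrix)
  lines[3] <- "g1\t1.5\tNA\t3\t4.125"
  writeLines(lines, fx2$matrix)
  expect_error(read_expression(fx2$matrix, fx2$annotation),
               "non-numeric or missing")

  fx3 <- write_fixture()
  lines <- readLines(fx3$matrix)
  lines[4] <- "g1\t5\t6\t7\t8" # duplicate gene id
  writeLines(lines, fx3$matrix)
  expect_error(read_expression(fx3$matrix, fx3$annotation), "duplicate gene")
})

test_that("a transposed matrix is rejected rather than silently fixed", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tg1\tg2", "sA\t1\t2", "sB\t3\t4"),
             file.path(dir, "t.tsv"))
  writeLines(c("sample_id\toutcome", "sA\t0", "sB\t1"),
             file.path(dir, "a.tsv"))
  expect_error(read_expression(file.path(dir, "t.tsv"), file.path(dir, "a.tsv")),
               "transposed")
})

test_that("read -> write -> read round-trips finite decimal values exactly", {
  fx <- write_fixture()
  ds <- read_expression(fx$matrix, fx$annotation)
  mp2 <- file.path(fx$dir, "out.tsv"); ap2 <- file.path(fx$dir, "outann.tsv")
  write_expression(ds, mp2, ap2)
  ds2 <- read_expression(mp2, ap2)
  expect_identical(ds2$values, ds$values)
  expect_equal(ds2$annotations$outcome, ds$annotations$outcome)
})

test_that("zscore_genes standardises rows and is idempotent", {
  ds <- make_ds(rbind(c(1, 2, 3), c(10, 20, 60)), c(0, 1, 1))
  z <- zscore_genes(ds)
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(z$values)), c(0, 0))
  expect_equal(unname(apply(z$values, 1, sd)), c(1, 1))
  z2 <- zscore_genes(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)

  flat <- make_ds(rbind(c(5, 5, 5), c(1, 2, 3)), c(0, 1, 1))
  expect_error(zscore_genes(flat), "g1")
})

test_that("subsetting restricts and reorders; unknown ids are named errors", {
  ds <- make_ds(matrix(1:12, 3, 4), c(0, 0, 1, 1))
  expect_equal(ds[c("g1", "g2", "g3"), ]$values, ds$values)
  sub <- ds["g2", c("s4", "s1")]
  expect_equal(dim(sub), c(1L, 2L))
  expect_equal(unname(sub$values[1, ]), c(11, 2))
  expect_equal(sub$annotations$outcome, c(1L, 0L))
  expect_error(ds["g999", ], "g999")
  expect_error(ds[, "s99"], "s99")
  # subset of subset equals the combined subset
  a <- ds[c("g3", "g1"), c("s2", "s3")]["g1", "s3"]
  b <- ds["g1", "s3"]
  expect_identical(a$values, b$values)
})
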