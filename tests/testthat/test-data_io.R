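make_dense_csv <- function(m, path) {
  df <- data.frame(barcode = rownames(m), as.data.frame(m), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("dense CSV round trip preserves values and identifiers", {
  m <- matrix(c(0, 1.5, 2, 0.25, 3, 0, 4, 1, 2, 0, 0, 5), 3, 4,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  path <- make_dense_csv(m, tempfile(fileext = ".csv"))
  x <- load_expression(path)
  expect_equal(dim(x), c(3L, 4L))
  expect_equal(unname(x), unname(m))
  expect_identical(rownames(x), rownames(m))
  expect_identical(colnames(x), colnames(m))
})

test_that("MTX triplets with explicit zeros equal the dense encoding", {
  m <- matrix(c(1, 0, 0.5, 2, 0, 0, 3, 1.25), 2, 4,
              dimnames = list(c("b1", "b2"), paste0("g", 1:4)))
  dir <- tempfile(); dir.create(dir)
  mtx <- file.path(dir, "matrix.mtx")
  sp <- Matrix::Matrix(t(m), sparse = TRUE)      # genes x cells, CellRanger-style
  Matrix::writeMM(sp, mtx)
  # append two explicit zero entries
  lines <- readLines(mtx)
  hdr <- strsplit(lines[2], " ")[[1]]
  hdr[3] <- as.integer(hdr[3]) + 2L
  lines[2] <- paste(hdr, collapse = " ")
  writeLines(c(lines, "2 1 0", "3 2 0"), mtx)
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  x <- load_expression(mtx)
  dense <- load_expression(make_dense_csv(m, tempfile(fileext = ".csv")))
  expect_equal(x, dense)
})

test_that("negative entries and identifier mismatches are rejected", {
  m <- matrix(c(1, -0.5, 2, 3), 2, 2,
              dimnames = list(c("c1", "c2"), c("g1", "g2")))
  path <- make_dense_csv(m, tempfile(fileext = ".csv"))
  expect_error(load_expression(path), "negative")
  dir <- tempfile(); dir.create(dir)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(matrix(1, 3, 2), sparse = TRUE), mtx)
  writeLines(c("b1", "b2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("g1", "g2", "g3", "g4"), file.path(dir, "features.tsv"))
  expect_error(load_expression(mtx), "sidecars")
})

test_that("qc_filter removes boundary cells inclusively and in order", {
  genes <- c("MT-1", paste0("g", 1:299))
  # cell A: mito fraction exactly 1/5 = 0.20 (removed by rule 1, so it is
  # attributed to the mitochondrial count even though it would also fail the
  # gene-count rule); cell B: exactly 250 genes expressed; cell C: clean
  A <- c(1, 4, rep(0, 298))
  B <- c(1, rep(1, 249), rep(0, 50))
  C <- c(0.1, rep(1, 299))
  expr <- rbind(A = A, B = B, C = C)
  colnames(expr) <- genes
  res <- qc_filter(expr, mito_gene_ids = "MT-1")
  expect_identical(rownames(res$expr), "C")
  expect_equal(res$report$n_removed_mito, 1L)
  expect_equal(res$report$n_removed_low_genes, 1L)
  expect_equal(res$report$n_cells_out, 1L)
})

test_that("qc_filter matches a brute-force scan on a 100-cell fixture", {
  set.seed(11)
  n_genes <- 400
  genes <- c("MT-A", "MT-B", paste0("g", seq_len(n_genes - 2)))
  base <- matrix(runif(100 * n_genes, 0.5, 2), 100, n_genes,
                 dimnames = list(sprintf("cell%03d", 1:100), genes))
  base[, 1:2] <- 0.01
  # 7 cells violate the mitochondrial rule
  for (i in 1:7) base[i, 1:2] <- sum(base[i, ]) # pushes fraction >= 0.2
  # 5 distinct cells violate the gene-count rule
  for (i in 8:12) base[i, 251:n_genes] <- 0
  res <- qc_filter(base, mito_gene_ids = c("MT-A", "MT-B"))
  keep <- brute_force_qc(base, c("MT-A", "MT-B"))
  expect_identical(rownames(res$expr), keep)
  expect_equal(res$report$n_cells_out, 88L)
  expect_equal(res$report$n_removed_mito, 7L)
  expect_equal(res$report$n_removed_low_genes, 5L)
  expect_equal(res$report$n_cells_in,
               res$report$n_cells_out + res$report$n_removed_mito +
                 res$report$n_removed_low_genes)
  # idempotence
  res2 <- qc_filter(res$expr, mito_gene_ids = c("MT-A", "MT-B"))
  expect_equal(res2$expr, res$expr)
  expect_equal(res2$report$n_removed_mito + res2$report$n_removed_low_genes, 0L)
})

test_that("mito_genes matches the conventional prefix case-insensitively", {
  ids <- c("MT-CO1", "mt-Nd1", "MTND", "ACTB")
  expect_identical(mito_genes(ids), c("MT-CO1", "mt-Nd1"))
})

test_that("split_cells partitions deterministically with floor rounding", {
  ids <- paste0("c", 1:10)
  sp <- split_cells(ids, 0.7, seed = 3)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp$train, split_cells(ids, 0.7, seed = 3)$train)
  expect_error(split_cells(ids, 1.2), "between 0 and 1")
  expect_length(split_cells(paste0("c", 1:8552), 0.7, seed = 1)$train, 5986)
})

test_that("split_cells partitions hold across many seeds", {
  ids <- paste0("c", 1:37)
  for (seed in 1:100) {
    sp <- split_cells(ids, 0.61, seed = seed)
    expect_length(c(sp$train, sp$test), 37)
    expect_length(intersect(sp$train, sp$test), 0)
  }
})

test_that("prior-feature loading follows the absence and symmetry conventions", {
  path <- tempfile(fileext = ".tsv")
  # empty table (header only)
  writeLines("protein_a\tprotein_b\tscore1\tscore2", path)
  ps <- load_prior_features(path, paste0("P", 1:3))
  expect_length(ps$features, 2)
  for (m in ps$features) expect_equal(unname(m), matrix(0, 3, 3))

  writeLines(c("protein_a\tprotein_b\tcombined\ttextmining",
               "P1\tP2\t0.9\t0.4",
               "P1\tP1\t0.8\t0.8",       # self edge: ignored
               "P9\tP1\t1.0\t1.0"),      # outside the panel: ignored
             path)
  ps <- load_prior_features(path, paste0("P", 1:3))
  m <- ps$features$combined
  expect_equal(m["P1", "P2"], 0.9)
  expect_equal(m["P2", "P1"], 0.9)
  expect_equal(diag(m), c(P1 = 0, P2 = 0, P3 = 0))
  expect_equal(unname(m["P3", ]), c(0, 0, 0))   # absent protein: zero row
  expect_equal(unname(m[, "P3"]), c(0, 0, 0))
  expect_true(isSymmetric(ps$features$textmining))
  expect_error(load_prior_features(path, paste0("P", 1:3), "nope"),
               "available: combined, textmining")
})

test_that("STRING 0-1000 integer scores are rescaled to 0-1", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tcombined",
               "P1\tP2\t900", "P2\tP3\t150"), path)
  ps <- load_prior_features(path, paste0("P", 1:3))
  expect_equal(ps$features$combined["P1", "P2"], 0.9)
  expect_equal(ps$features$combined["P2", "P3"], 0.15)
})
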