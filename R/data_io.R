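#' Load a cells x genes expression matrix
#'
#' Reads single-cell expression values from either a dense delimited table
#' (first column = cell barcode, header row = gene identifiers) or a
#' MatrixMarket `.mtx` triplet file with CellRanger-style `barcodes.tsv` /
#' `features.tsv` (or `genes.tsv`) sidecars in the same directory.  The result
#' is always oriented cells x genes; for MTX input the orientation is
#' auto-detected from the sidecar lengths and an explicit `orientation` is
#' required when the matrix is square and the sidecars cannot disambiguate.
#'
#' @param path Path to the CSV/TSV table or the `.mtx` file.
#' @param format `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @param orientation For MTX input only: `"genes_by_cells"` (CellRanger
#'   convention) or `"cells_by_genes"`; ignored when the sidecars already
#'   determine it.
#' @return A numeric matrix, cells in rows (named by barcode), genes in
#'   columns (named by feature identifier).  Values must be non-negative.
#' @export
load_expression <- function(path,
                            format = c("auto", "dense", "mtx"),
                            orientation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  x <- if (format == "mtx") {
    read_expression_mtx(path, orientation)
  } else {
    read_expression_dense(path)
  }
  validate_expression(x)
  x
}

read_expression_dense <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (ncol(tab) < 2L)
    stop("expected a barcode column plus at least one gene column in ",
         path, call. = FALSE)
  barcodes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric expression values in column '",
         colnames(tab)[-1L][bad], "' of ", path, call. = FALSE)
  }
  rownames(vals) <- barcodes
  storage.mode(vals) <- "double"
  vals
}

read_expression_mtx <- function(path, orientation = NULL) {
  dir <- dirname(path)
  barcode_file <- file.path(dir, "barcodes.tsv")
  feature_file <- file.path(dir, "features.tsv")
  if (!file.exists(feature_file)) feature_file <- file.path(dir, "genes.tsv")
  if (!file.exists(barcode_file) || !file.exists(feature_file))
    stop("MTX input needs barcodes.tsv and features.tsv (or genes.tsv) ",
         "next to ", path, call. = FALSE)
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("could not parse ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  m <- as.matrix(m)
  barcodes <- readLines(barcode_file)
  feat_tab <- utils::read.table(feature_file, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  features <- as.character(feat_tab[[1L]])
  nb <- length(barcodes); nf <- length(features)
  fits_gc <- nrow(m) == nf && ncol(m) == nb   # genes x cells
  fits_cg <- nrow(m) == nb && ncol(m) == nf   # cells x genes
  if (fits_gc && fits_cg) {
    if (is.null(orientation))
      stop("matrix is ", nrow(m), " x ", ncol(m),
           " and the sidecars cannot disambiguate orientation; ",
           "pass orientation = \"genes_by_cells\" or \"cells_by_genes\"",
           call. = FALSE)
    orientation <- match.arg(orientation, c("genes_by_cells", "cells_by_genes"))
    fits_gc <- orientation == "genes_by_cells"
  } else if (!fits_gc && !fits_cg) {
    stop_dims(paste0("matrix is %d x %d but sidecars list %d barcodes and ",
                     "%d features"), nrow(m), ncol(m), nb, nf)
  }
  if (fits_gc) m <- t(m)
  rownames(m) <- barcodes
  colnames(m) <- features
  storage.mode(m) <- "double"
  m
}

validate_expression <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  if (any(x < 0))
    stop("expression matrix contains negative values; expected denoised ",
         "non-negative expression", call. = FALSE)
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x)))
    stop("gene identifiers are not unique", call. = FALSE)
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("cell identifiers are not unique", call. = FALSE)
  invisible(x)
}

#' Identify mitochondrial genes by identifier prefix
#'
#' Convenience wrapper around the conventional "MT-" naming (case-insensitive,
#' so mouse "mt-" symbols also match).  For other species or identifier
#' schemes pass an explicit identifier set to [qc_filter()].
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param prefix Prefix marking mitochondrial genes (default `"MT-"`).
#' @return The subset of `gene_ids` with the prefix.
#' @export
mito_genes <- function(gene_ids, prefix = "MT-") {
  gene_ids[startsWith(toupper(gene_ids), toupper(prefix))]
}

#' Quality-control filter for cells
#'
#' Removes, in order: (1) cells whose mitochondrial read fraction is at least
#' `max_mito_rate` (inclusive); then (2) cells expressing at most `min_genes`
#' genes (inclusive), where "expressed" means a strictly positive value.
#' Cells with zero total signal have mitochondrial fraction 0 and are caught
#' by the gene-count rule.
#'
#' @param expr Cells x genes matrix (see [load_expression()]).
#' @param mito_gene_ids Identifiers of mitochondrial genes; must be a subset
#'   of `colnames(expr)`.  May be empty, in which case rule (1) removes
#'   nothing.
#' @param max_mito_rate Mitochondrial-fraction threshold (default 0.20).
#' @param min_genes Expressed-gene threshold (default 250).
#' @return A list with `expr` (the filtered matrix) and `report`, a
#'   `qc_report` with fields `n_cells_in`, `n_removed_mito`,
#'   `n_removed_low_genes`, `n_cells_out`.
#' @export
qc_filter <- function(expr, mito_gene_ids = character(),
                      max_mito_rate = 0.20, min_genes = 250) {
  expr <- as_dense_matrix(expr, "expr")
  if (length(mito_gene_ids) &&
      !all(mito_gene_ids %in% colnames(expr)))
    stop("mito_gene_ids not found in gene identifiers: ",
         paste(setdiff(mito_gene_ids, colnames(expr)), collapse = ", "),
         call. = FALSE)
  n_in <- nrow(expr)
  tot <- rowSums(expr)
  mito <- if (length(mito_gene_ids))
    rowSums(expr[, mito_gene_ids, drop = FALSE]) else numeric(n_in)
  rate <- ifelse(tot > 0, mito / tot, 0)
  drop1 <- rate >= max_mito_rate
  kept <- expr[!drop1, , drop = FALSE]
  n_expressed <- rowSums(kept > 0)
  drop2 <- n_expressed <= min_genes
  out <- kept[!drop2, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("quality-control filters removed every cell", call. = FALSE)
  report <- structure(
    list(n_cells_in = n_in,
         n_removed_mito = sum(drop1),
         n_removed_low_genes = sum(drop2),
         n_cells_out = nrow(out)),
    class = "qc_report")
  list(expr = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Cell quality control\n")
  cat("  cells in:                 ", x$n_cells_in, "\n")
  cat("  removed (mito fraction):  ", x$n_removed_mito, "\n")
  cat("  removed (low gene count): ", x$n_removed_low_genes, "\n")
  cat("  cells out:                ", x$n_cells_out, "\n")
  invisible(x)
}

#' Random train/test split of cells
#'
#' Draws `floor(train_fraction * C)` cells uniformly without replacement into
#' the training set (clamped to leave at least one cell on each side); the
#' rest form the test set.  Deterministic given `seed`.  The floor convention
#' is a fixed package choice; published 70:30 splits rounded differently are
#' not reconstructable in general.
#'
#' @param cell_ids Character vector of cell identifiers (>= 2, unique).
#' @param train_fraction Fraction of cells to train on, in (0, 1).
#' @param seed Integer seed.
#' @return A `cell_split` list: `train`, `test`, `seed`.
#' @export
split_cells <- function(cell_ids, train_fraction = 0.7, seed = 1L) {
  if (length(cell_ids) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique", call. = FALSE)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  n <- length(cell_ids)
  n_train <- min(max(floor(train_fraction * n), 1L), n - 1L)
  train <- with_seed(seed, sample(cell_ids, n_train))
  structure(list(train = train,
                 test = setdiff(cell_ids, train),
                 seed = as.integer(seed)),
            class = "cell_split")
}

#' @export
print.cell_split <- function(x, ...) {
  cat(sprintf("Cell split (seed %d): %d train / %d test\n",
              x$seed, length(x$train), length(x$test)))
  invisible(x)
}

#' Construct a prior-feature set from adjacency matrices
#'
#' @param matrices Named list of symmetric N x N matrices of non-negative
#'   finite scores, rows/columns indexed by `protein_ids`.
#' @param protein_ids Protein identifiers (length N).
#' @return A `prior_feature_set`.
#' @export
prior_feature_set <- function(matrices, protein_ids) {
  if (!length(matrices)) stop("need at least one prior feature", call. = FALSE)
  if (is.null(names(matrices)))
    names(matrices) <- paste0("feature_", seq_along(matrices))
  n <- length(protein_ids)
  for (nm in names(matrices)) {
    m <- as_dense_matrix(matrices[[nm]], nm)
    if (!all(dim(m) == c(n, n)))
      stop_dims("prior feature '%s' is %d x %d, expected %d x %d",
                nm, nrow(m), ncol(m), n, n)
    if (any(!is.finite(m)) || any(m < 0))
      stop("prior feature '", nm, "' has negative or non-finite scores",
           call. = FALSE)
    if (max(abs(m - t(m))) > 1e-12)
      stop("prior feature '", nm, "' is not symmetric", call. = FALSE)
    dimnames(m) <- list(protein_ids, protein_ids)
    matrices[[nm]] <- m
  }
  structure(list(features = matrices,
                 protein_ids = as.character(protein_ids)),
            class = "prior_feature_set")
}

#' @export
print.prior_feature_set <- function(x, ...) {
  cat(sprintf("Prior feature set: %d feature(s) over %d proteins\n",
              length(x$features), length(x$protein_ids)))
  cat("  features:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Load prior-knowledge features from a STRING-style edge list
#'
#' Reads a TSV with columns `protein_a`, `protein_b` and one numeric score
#' column per feature, and builds one symmetric N x N matrix per requested
#' feature over the panel `protein_ids`.  Pairs absent from the table score 0;
#' panel proteins absent from the table get an all-zero row and column;
#' self-scores are fixed at 0.  Edges mentioning proteins outside the panel
#' are ignored.  Scores on the STRING 0-1000 integer scale are detected per
#' feature (any score > 1) and divided by 1000; duplicate pairs keep the
#' maximum score.
#'
#' @param path Path to the TSV edge list.
#' @param protein_ids Panel protein identifiers (the matrix index).
#' @param feature_columns Which score columns to load; default all columns
#'   after `protein_a`/`protein_b`.
#' @return A [prior_feature_set()].
#' @export
load_prior_features <- function(path, protein_ids, feature_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("protein_a", "protein_b")
  if (!all(need %in% colnames(tab)))
    stop("edge table must have columns protein_a and protein_b", call. = FALSE)
  available <- setdiff(colnames(tab), need)
  if (is.null(feature_columns)) feature_columns <- available
  unknown <- setdiff(feature_columns, available)
  if (length(unknown))
    stop("unknown feature column(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  n <- length(protein_ids)
  keep <- tab$protein_a %in% protein_ids &
    tab$protein_b %in% protein_ids &
    tab$protein_a != tab$protein_b
  tab <- tab[keep, , drop = FALSE]
  mats <- lapply(feature_columns, function(fc) {
    m <- matrix(0, n, n, dimnames = list(protein_ids, protein_ids))
    sc <- as.numeric(tab[[fc]])
    sc[is.na(sc)] <- 0
    if (length(sc) && any(sc > 1)) sc <- sc / 1000
    for (k in seq_along(sc)) {
      a <- tab$protein_a[k]; b <- tab$protein_b[k]
      v <- max(m[a, b], sc[k])
      m[a, b] <- v
      m[b, a] <- v
    }
    m
  })
  names(mats) <- feature_columns
  prior_feature_set(mats, protein_ids)
}

# --- writers (used by the simulator CLI so round trips are testable) -------

write_expression_csv <- function(expr, path) {
  df <- data.frame(barcode = rownames(expr),
                   as.data.frame(expr, check.names = FALSE),
                   check.names = FALSE)
  write_atomic(path, function(p)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE))
}

write_prior_features_tsv <- function(priors, path) {
  ids <- priors$protein_ids
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- data.frame(protein_a = ids[idx[, 1L]],
                     protein_b = ids[idx[, 2L]])
  for (nm in names(priors$features))
    rows[[nm]] <- priors$features[[nm]][idx]
  keep <- rowSums(as.matrix(rows[, -(1:2), drop = FALSE])) > 0
  rows <- rows[keep, , drop = FALSE]
  write_atomic(path, function(p)
    utils::write.table(rows, p, sep = "\t", row.names = FALSE, quote = FALSE))
}
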