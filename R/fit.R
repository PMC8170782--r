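#' Fit a PPI-informed graph neural network for RNA-to-protein prediction
#'
#' Trains the full network — RNA encoder, per-protein heads, prior-knowledge
#' embedding (when `priors` is supplied), one round of graph propagation with
#' a trainable adjacency, and a shared PReLU predictor — by minibatch Adam on
#' the mean-squared-error loss, keeping the parameters of the epoch with the
#' smallest training loss (best-epoch checkpointing).
#'
#' @param x Cells x genes matrix of non-negative denoised RNA expression.
#' @param y Cells x proteins matrix of log-like (possibly negative) protein
#'   abundances, rows aligned with `x`.
#' @param priors Optional [prior_feature_set()] over the proteins of `y`;
#'   `NULL` fits the model without prior knowledge.
#' @param config A [train_config()].
#' @param seed Integer seed governing initialisation and batch shuffling;
#'   identical seeds give identical fits.
#' @return An object of class `"protein_gnn"` with `params` (best-epoch
#'   checkpoint), `history` (per-epoch training loss), `best_epoch`,
#'   `best_loss`, `fitted.values`, `residuals`, `config`, `dims`,
#'   `gene_ids`, `protein_ids`, `priors` and `seed`.
#' @seealso [predict.protein_gnn()], [evaluate_model()], [simulate_citeseq()]
#' @export
protein_gnn <- function(x, y, priors = NULL, config = train_config(),
                        seed = 1L) {
  x <- as_dense_matrix(x, "x")
  y <- as_dense_matrix(y, "y")
  if (nrow(x) != nrow(y))
    stop_dims("x has %d cells but y has %d", nrow(x), nrow(y))
  if (ncol(y) < 2L) stop("need at least 2 proteins", call. = FALSE)
  if (any(x < 0))
    stop("x contains negative values; expected denoised expression",
         call. = FALSE)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y)))
      stop("x and y carry different cell identifiers", call. = FALSE)
    y <- y[rownames(x), , drop = FALSE]
  }
  if (!is.null(priors)) {
    if (!inherits(priors, "prior_feature_set"))
      stop("`priors` must be a prior_feature_set", call. = FALSE)
    if (!is.null(colnames(y))) {
      if (!setequal(priors$protein_ids, colnames(y)))
        stop("priors cover proteins ",
             paste(priors$protein_ids, collapse = ", "),
             " but y has ", paste(colnames(y), collapse = ", "),
             call. = FALSE)
      priors$features <- lapply(priors$features, function(m)
        m[colnames(y), colnames(y)])
      priors$protein_ids <- colnames(y)
    } else if (length(priors$protein_ids) != ncol(y)) {
      stop_dims("priors cover %d proteins but y has %d",
                length(priors$protein_ids), ncol(y))
    }
  }
  tr <- train_model(x, y, priors, config, seed)
  fitted <- forward_pass(tr$params, x, priors)$yhat
  dimnames(fitted) <- dimnames(y)
  structure(
    list(params = tr$params,
         history = tr$history,
         best_epoch = tr$best_epoch,
         best_loss = tr$best_loss,
         fitted.values = fitted,
         residuals = y - fitted,
         config = config,
         dims = tr$params$meta,
         gene_ids = colnames(x),
         protein_ids = colnames(y) %||%
           paste0("protein_", seq_len(ncol(y))),
         priors = priors,
         seed = as.integer(seed),
         call = match.call()),
    class = "protein_gnn")
}

#' @export
print.protein_gnn <- function(x, ...) {
  m <- x$dims
  cat("PPI-informed graph neural network for RNA-to-protein prediction\n")
  cat(sprintf("  genes: %d  proteins: %d  prior features: %d\n",
              m$n_genes, m$n_proteins, m$n_features))
  cat(sprintf("  encoder %d -> %d -> %d; d_r = %d, d_c = %d, d_k = %d, d = %d\n",
              m$n_genes, m$hidden[1], m$hidden[2], m$d_r, m$d_c, m$d_k, m$d))
  cat(sprintf("  checkpoint: epoch %d of %d (training loss %.5g)\n",
              x$best_epoch, length(x$history), x$best_loss))
  invisible(x)
}

#' @export
summary.protein_gnn <- function(object, ...) {
  res <- eval_metrics(object$fitted.values + object$residuals,
                      object$fitted.values)
  out <- list(fit = object, train_metrics = res)
  class(out) <- "summary.protein_gnn"
  out
}

#' @export
print.summary.protein_gnn <- function(x, ...) {
  print(x$fit)
  cat("Training-set metrics:\n")
  print(x$train_metrics)
  invisible(x)
}

#' @export
coef.protein_gnn <- function(object, ...) {
  p <- object$params
  p[setdiff(names(p), "meta")]
}

#' Predict protein abundances for new cells
#'
#' @param object A fitted [protein_gnn()] model.
#' @param newdata Cells x genes matrix; the gene dimension must match the
#'   fit (columns are reordered by name when identifiers are available).
#' @param ... Unused.
#' @return Cells x proteins matrix of predicted abundances.
#' @export
predict.protein_gnn <- function(object, newdata, ...) {
  newdata <- as_dense_matrix(newdata, "newdata")
  G <- object$dims$n_genes
  if (!is.null(colnames(newdata)) && !is.null(object$gene_ids) &&
      setequal(colnames(newdata), object$gene_ids)) {
    newdata <- newdata[, object$gene_ids, drop = FALSE]
  }
  if (ncol(newdata) != G)
    stop_dims("gene dimension mismatch: model expects %d genes, input has %d",
              G, ncol(newdata))
  yhat <- forward_pass(object$params, newdata, object$priors)$yhat
  dimnames(yhat) <- list(rownames(newdata), object$protein_ids)
  yhat
}

#' @export
fitted.protein_gnn <- function(object, ...) object$fitted.values

#' @export
residuals.protein_gnn <- function(object, ...) object$residuals

#' Plot the training loss history
#'
#' @param x A fitted [protein_gnn()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.protein_gnn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training MSE loss", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey40")
  graphics::points(x$best_epoch, x$best_loss, pch = 19)
  invisible(x)
}

#' Evaluate a fitted model on held-out cells
#'
#' @param object A fitted [protein_gnn()] model.
#' @param x Cells x genes expression of the held-out cells.
#' @param y Matching cells x proteins ground truth.
#' @return A `run_result` (see [eval_metrics()]).
#' @export
evaluate_model <- function(object, x, y) {
  yhat <- predict(object, x)
  eval_metrics(as_dense_matrix(y, "y"), yhat)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing file holding every parameter
#' array, the architecture metadata, the prior-feature matrices and the
#' package version; reloading reproduces predictions bit-identically on the
#' same platform.
#'
#' @param object A fitted [protein_gnn()] model.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `protein_gnn` object.
#' @export
save_checkpoint <- function(object, path) {
  if (!inherits(object, "protein_gnn"))
    stop("`object` must be a fitted protein_gnn model", call. = FALSE)
  payload <- list(format = "protgnn-checkpoint", version = 1L,
                  package_version = as.character(utils::packageVersion("protgnn")),
                  fit = object)
  write_atomic(path, function(p) saveRDS(payload, p))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- readRDS(path)
  if (!identical(payload$format, "protgnn-checkpoint"))
    stop(path, " is not a protgnn checkpoint", call. = FALSE)
  payload$fit
}
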