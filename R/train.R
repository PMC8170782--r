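#' Mean-squared-error loss
#'
#' For each cell, the squared prediction error is summed over the N proteins
#' (all proteins weighted equally); the per-cell sums are then averaged over
#' the batch so the magnitude does not depend on batch size.
#'
#' @param y_true,y_pred B x N matrices.
#' @return Non-negative scalar; zero iff the matrices are identical.
#' @examples
#' mse_loss(matrix(c(1, 2), 1), matrix(c(2, 0), 1))  # 1 + 4 = 5
#' @export
mse_loss <- function(y_true, y_pred) {
  if (!identical(dim(y_true), dim(y_pred)))
    stop_dims("y_true is %d x %d but y_pred is %d x %d",
              nrow(y_true), ncol(y_true), nrow(y_pred), ncol(y_pred))
  sum((y_pred - y_true)^2) / nrow(y_true)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  nm <- setdiff(names(params), "meta")
  zeros <- lapply(params[nm], function(p) p * 0)   # keeps each array's shape
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    gi <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gi
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gi^2
    step <- lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference hyperparameters: encoder hidden sizes
#' 1024/128, `d_r = 64`, `d_c = 32`, learning rate 1e-6, batch size 32,
#' 350 epochs, Adam, PReLU slope 0.25.  Desk-scale synthetic benchmarks use
#' smaller widths and a larger learning rate (see [holdout_benchmark()]).
#'
#' @param epochs Number of passes over the training cells (>= 1).
#' @param batch_size Cells per minibatch (>= 1).
#' @param learning_rate Positive Adam step size.
#' @param hidden Two encoder hidden sizes.
#' @param d_r,d_c Representation widths.
#' @param prelu_slope PReLU negative slope.
#' @param optimizer Only `"adam"` is provided.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 350L, batch_size = 32L,
                        learning_rate = 1e-6, hidden = c(1024L, 128L),
                        d_r = 64L, d_c = 32L, prelu_slope = 0.25,
                        optimizer = "adam") {
  optimizer <- match.arg(optimizer, "adam")
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stop("learning_rate must be non-negative", call. = FALSE)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, hidden = as.integer(hidden),
                 d_r = as.integer(d_r), d_c = as.integer(d_c),
                 prelu_slope = prelu_slope, optimizer = optimizer),
            class = "train_config")
}

# Core training loop: minibatch Adam on the MSE loss with best-epoch
# checkpointing.  The epoch-level loss compared for checkpointing is the mean
# of the minibatch losses within the epoch; ties keep the earlier epoch.
# Everything (init, shuffling) runs in one RNG stream seeded once, so runs
# are reproducible from `seed` alone.
train_model <- function(x, y, priors = NULL, config = train_config(),
                        seed = 1L) {
  B <- config$batch_size
  dimnames(x) <- NULL   # keep identifiers out of the parameter arrays
  dimnames(y) <- NULL
  with_seed(seed, {
    params <- init_model_params(
      n_genes = ncol(x), n_proteins = ncol(y),
      n_features = if (is.null(priors)) 0L else length(priors$features),
      hidden = config$hidden, d_r = config$d_r, d_c = config$d_c,
      use_prior = !is.null(priors), prelu_slope = config$prelu_slope,
      seed = NULL)
    state <- adam_init(params)
    n_cells <- nrow(x)
    history <- numeric(config$epochs)
    best_loss <- Inf; best_params <- params; best_epoch <- NA_integer_
    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n_cells)
      starts <- seq(1L, n_cells, by = B)
      loss_sum <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + B - 1L, n_cells)]
        fb <- loss_and_grads(params, x[idx, , drop = FALSE],
                             y[idx, , drop = FALSE], priors)
        if (!is.finite(fb$loss))
          stop(sprintf("non-finite training loss at epoch %d, batch %d", e, bi),
               call. = FALSE)
        loss_sum <- loss_sum + fb$loss * length(idx)
        upd <- adam_step(params, fb$grads, state, config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      # size-weighted so the epoch loss equals the mean per-cell loss and
      # does not depend on how the shuffle partitions cells into batches
      history[e] <- loss_sum / n_cells
      if (history[e] < best_loss) {
        best_loss <- history[e]
        best_params <- params
        best_epoch <- e
      }
    }
    list(params = best_params, best_epoch = best_epoch, best_loss = best_loss,
         history = history, final_params = params)
  })
}

#' Pick the checkpointed epoch from a loss history
#'
#' @param history Numeric vector of per-epoch losses.
#' @return Index of the first minimum (ties keep the earlier epoch).
#' @export
best_epoch <- function(history) which.min(history)

#' Per-protein evaluation of predictions
#'
#' For every protein: MSE (mean over cells of the squared error) and the
#' Pearson correlation across cells between truth and prediction.  Summary
#' rows report the mean and sample (n-1) standard deviation over proteins.
#' A protein whose truth or prediction is constant across cells has an
#' undefined correlation: it is reported as `NA` with a warning and excluded
#' from the PCC mean/SD (its MSE still counts).
#'
#' @param y_true,y_pred Cells x proteins matrices.
#' @return A `run_result`: `per_protein` data frame (protein, mse, pcc) plus
#'   `mse_mean`, `mse_sd`, `pcc_mean`, `pcc_sd`, `n_cells`.
#' @export
eval_metrics <- function(y_true, y_pred) {
  if (!identical(dim(y_true), dim(y_pred)))
    stop_dims("y_true is %d x %d but y_pred is %d x %d",
              nrow(y_true), ncol(y_true), nrow(y_pred), ncol(y_pred))
  n <- ncol(y_true)
  ids <- colnames(y_true) %||% paste0("protein_", seq_len(n))
  mse <- colMeans((y_pred - y_true)^2)
  pcc <- vapply(seq_len(n), function(i) {
    if (stats::sd(y_true[, i]) == 0 || stats::sd(y_pred[, i]) == 0)
      return(NA_real_)
    stats::cor(y_true[, i], y_pred[, i])
  }, numeric(1))
  if (anyNA(pcc))
    warning("Pearson correlation undefined (constant values) for: ",
            paste(ids[is.na(pcc)], collapse = ", "),
            "; excluded from the PCC summary", call. = FALSE)
  structure(
    list(per_protein = data.frame(protein = ids, mse = unname(mse),
                                  pcc = pcc, stringsAsFactors = FALSE),
         mse_mean = mean(mse), mse_sd = stats::sd(mse),
         pcc_mean = mean(pcc, na.rm = TRUE),
         pcc_sd = stats::sd(pcc[!is.na(pcc)]),
         n_cells = nrow(y_true)),
    class = "run_result")
}

#' @export
print.run_result <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation over %d cells, %d proteins\n",
              x$n_cells, nrow(x$per_protein)))
  print(format(x$per_protein, digits = digits), row.names = FALSE)
  cat(sprintf("  MSE  mean %.4f (SD %.4f)\n", x$mse_mean, x$mse_sd))
  cat(sprintf("  PCC  mean %.4f (SD %.4f)\n", x$pcc_mean, x$pcc_sd))
  invisible(x)
}

#' Best-of-k run summary
#'
#' Following the evaluation protocol, for each protein the smallest MSE and
#' the largest PCC across the k runs are selected independently (they may
#' come from different runs), then summarised by mean and sample SD across
#' proteins.
#'
#' @param results List of `run_result` objects over the same proteins.
#' @return A `run_result` holding the per-protein best values.
#' @export
best_of_runs <- function(results) {
  if (!length(results)) stop("empty result list", call. = FALSE)
  per <- lapply(results, `[[`, "per_protein")
  ids <- per[[1L]]$protein
  for (p in per)
    if (!identical(p$protein, ids))
      stop("runs disagree on the protein panel", call. = FALSE)
  mse <- apply(vapply(per, `[[`, numeric(length(ids)), "mse"), 1L, min)
  pcc_mat <- vapply(per, `[[`, numeric(length(ids)), "pcc")
  pcc_mat <- matrix(pcc_mat, nrow = length(ids))
  pcc <- apply(pcc_mat, 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  structure(
    list(per_protein = data.frame(protein = ids, mse = mse, pcc = pcc,
                                  stringsAsFactors = FALSE),
         mse_mean = mean(mse), mse_sd = stats::sd(mse),
         pcc_mean = mean(pcc, na.rm = TRUE),
         pcc_sd = stats::sd(pcc[!is.na(pcc)]),
         n_cells = results[[1L]]$n_cells),
    class = "run_result")
}
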