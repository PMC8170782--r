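make_tiny_task <- function(n_cells = 60, G = 6, N = 3, seed = 51) {
  set.seed(seed)
  X <- matrix(runif(n_cells * G), n_cells, G,
              dimnames = list(sprintf("c%03d", 1:n_cells), paste0("g", 1:G)))
  W <- matrix(rnorm(G * N), G, N)
  Y <- scale(X %*% W, scale = FALSE) + matrix(rnorm(n_cells * N, 0, 0.05),
                                              n_cells, N)
  Y <- matrix(as.numeric(Y), n_cells, N,
              dimnames = list(rownames(X), paste0("P", 1:N)))
  list(x = X, y = Y)
}

tiny_fit_config <- function(epochs = 25)
  train_config(epochs = epochs, batch_size = 16, learning_rate = 1e-3,
              hidden = c(8, 6), d_r = 2, d_c = 2)

test_that("mse_loss is the batch mean of per-cell protein error sums", {
  a <- matrix(c(1, 2), 1)
  b <- matrix(c(2, 0), 1)
  expect_equal(mse_loss(a, b), 5)           # 1 + 4
  expect_equal(mse_loss(a, a), 0)
  # homogeneity: scaling residuals by c scales the loss by c^2
  y <- matrix(rnorm(8), 4, 2); yh <- matrix(rnorm(8), 4, 2)
  expect_equal(mse_loss(y, y + 3 * (yh - y)), 9 * mse_loss(y, yh))
  # batch-size independence
  expect_equal(mse_loss(rbind(a, a), rbind(b, b)), 5)
  expect_error(mse_loss(a, matrix(0, 2, 2)), "1 x 2")
})

test_that("checkpoint selection takes the first minimum of the history", {
  expect_equal(best_epoch(c(5, 3, 4, 2, 6)), 4L)
  expect_equal(best_epoch(c(2, 1, 1, 3)), 2L)  # ties keep the earlier epoch
  expect_equal(best_epoch(7), 1L)
})

test_that("training is reproducible, improves the loss, and checkpoints the minimum", {
  task <- make_tiny_task()
  pr <- tiny_priors(3, 2, seed = 52)
  f1 <- protein_gnn(task$x, task$y, pr, tiny_fit_config(), seed = 9)
  f2 <- protein_gnn(task$x, task$y, pr, tiny_fit_config(), seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_equal(f1$best_loss, min(f1$history))
  expect_equal(f1$best_epoch, which.min(f1$history))
  expect_lt(f1$best_loss, f1$history[1])
})

test_that("a zero learning rate freezes parameters and loss", {
  task <- make_tiny_task(n_cells = 24)
  cfg <- tiny_fit_config(epochs = 4)   # batch 16: unequal batches on purpose
  cfg$learning_rate <- 0
  fit <- protein_gnn(task$x, task$y, NULL, cfg, seed = 5)
  expect_equal(length(unique(round(fit$history, 12))), 1L)
  init <- protgnn:::with_seed(5, protgnn:::init_model_params(
    ncol(task$x), ncol(task$y), 0L, hidden = cfg$hidden, d_r = cfg$d_r,
    d_c = cfg$d_c, use_prior = FALSE, prelu_slope = cfg$prelu_slope,
    seed = NULL))
  expect_equal(fit$params$W1, init$W1)
  expect_equal(fit$params$A, init$A)
})

test_that("per-protein evaluation matches hand arithmetic", {
  y <- matrix(c(1, 2, 3, 4,
                0, 1, 0, 1), 4, 2,
              dimnames = list(NULL, c("Pa", "Pb")))
  yh <- matrix(c(1.5, 2.5, 2.5, 4.5,
                 0.2, 0.9, 0.1, 0.8), 4, 2)
  res <- eval_metrics(y, yh)
  expect_equal(res$per_protein$mse,
               c(mean(c(0.25, 0.25, 0.25, 0.25)),
                 mean(c(0.04, 0.01, 0.01, 0.04))))
  expect_equal(res$per_protein$pcc,
               c(cor(y[, 1], yh[, 1]), cor(y[, 2], yh[, 2])))
  expect_equal(res$mse_mean, mean(res$per_protein$mse))
  expect_equal(res$pcc_sd, sd(res$per_protein$pcc))
  # perfect and anti-correlated predictions
  perf <- eval_metrics(y, y)
  expect_equal(perf$per_protein$mse, c(0, 0))
  expect_equal(perf$per_protein$pcc, c(1, 1))
  anti <- eval_metrics(y, -y)
  expect_equal(anti$per_protein$pcc, c(-1, -1))
})

test_that("constant proteins yield NA correlations with a warning", {
  y <- cbind(a = c(1, 1, 1), b = c(0, 1, 2))
  yh <- cbind(a = c(0.5, 0.7, 0.2), b = c(0.1, 0.8, 2.2))
  expect_warning(res <- eval_metrics(y, yh), "constant.*a")
  expect_true(is.na(res$per_protein$pcc[1]))
  expect_equal(res$pcc_mean, res$per_protein$pcc[2])
})

test_that("reported per-protein MSE is consistent with the training loss", {
  set.seed(61)
  y <- matrix(rnorm(40), 10, 4)
  yh <- matrix(rnorm(40), 10, 4)
  res <- suppressWarnings(eval_metrics(y, yh))
  expect_equal(mean(res$per_protein$mse), mse_loss(y, yh) / ncol(y))
})

test_that("best-of-k selects each metric independently per protein", {
  mk <- function(mse, pcc)
    structure(list(per_protein = data.frame(protein = c("Pa", "Pb"),
                                            mse = mse, pcc = pcc),
                   n_cells = 10L), class = "run_result")
  runs <- list(mk(c(0.3, 1.0), c(0.9, 0.2)),
               mk(c(0.2, 1.2), c(0.5, 0.6)),
               mk(c(0.4, 0.9), c(0.7, 0.4)))
  best <- best_of_runs(runs)
  expect_equal(best$per_protein$mse, c(0.2, 0.9))
  expect_equal(best$per_protein$pcc, c(0.9, 0.6))  # from different runs
  one <- best_of_runs(runs[1])
  expect_equal(one$per_protein$mse, runs[[1]]$per_protein$mse)
  expect_equal(one$per_protein$pcc, runs[[1]]$per_protein$pcc)
  expect_error(best_of_runs(list()), "empty")
})
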