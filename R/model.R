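# Predictive network: RNA encoder (G -> hidden1 -> hidden2), N per-protein
# heads (hidden2 -> d_r), node construction (concatenate the head output with
# the per-protein knowledge embedding), one round of graph propagation
# V^e = sigmoid(A V W) with trainable A (N x N) and W (d x d), and a shared
# affine predictor d -> 1 through a PReLU.

#' Derived model dimensions
#'
#' The knowledge embedding has width `d_k = N * d_c` and each protein node
#' has width `d = d_r + d_k` (or `d = d_r` without prior knowledge).
#'
#' @param n_proteins Number of proteins N.
#' @param d_r Width of the RNA-derived protein representation (default 64).
#' @param d_c Encoding width per protein pair (default 32).
#' @param use_prior Whether a knowledge embedding is attached.
#' @return List with `d_r`, `d_c`, `d_k` and `d`.
#' @examples
#' model_dims(10)  # d_k = 320, d = 384
#' model_dims(13)  # d_k = 416, d = 480
#' @export
model_dims <- function(n_proteins, d_r = 64L, d_c = 32L, use_prior = TRUE) {
  d_k <- if (use_prior) as.integer(n_proteins) * as.integer(d_c) else 0L
  list(d_r = as.integer(d_r), d_c = as.integer(d_c),
       d_k = d_k, d = as.integer(d_r) + d_k)
}

#' Initialise all model parameters
#'
#' Weights are uniform, scaled by the reciprocal square root of each layer's
#' fan-in; biases start at zero.  The adjacency `A` and relation matrix `W`
#' of the graph layer are dense and fully trainable.
#'
#' @param n_genes Number of genes G.
#' @param n_proteins Number of proteins N (>= 2).
#' @param n_features Number of prior features M (ignored when
#'   `use_prior = FALSE`).
#' @param hidden Two hidden sizes of the RNA encoder (default `c(1024, 128)`).
#' @param d_r,d_c Representation widths (defaults 64 and 32).
#' @param use_prior Attach a knowledge embedding?
#' @param prelu_slope Negative slope of the PReLU activations (default 0.25).
#' @param seed Integer seed, or `NULL` to draw from the current RNG.
#' @return A named list of parameter arrays plus a `meta` entry recording the
#'   architecture.
#' @export
init_model_params <- function(n_genes, n_proteins, n_features = 0L,
                              hidden = c(1024L, 128L), d_r = 64L, d_c = 32L,
                              use_prior = n_features > 0L,
                              prelu_slope = 0.25, seed = NULL) {
  G <- as.integer(n_genes); n <- as.integer(n_proteins)
  h1 <- as.integer(hidden[1L]); h2 <- as.integer(hidden[2L])
  stopifnot(G >= 1L, n >= 2L, h1 >= 1L, h2 >= 1L)
  dims <- model_dims(n, d_r, d_c, use_prior)
  d <- dims$d
  with_seed(seed, {
    u <- function(nr, nc, fan) matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan), nr, nc)
    p <- list(
      W1 = u(G, h1, G), b1 = numeric(h1),
      W2 = u(h1, h2, h1), b2 = numeric(h2),
      Wh = array(stats::runif(h2 * dims$d_r * n, -1, 1) / sqrt(h2),
                 c(h2, dims$d_r, n)),
      bh = matrix(0, n, dims$d_r),
      A = u(n, n, n),
      W = u(d, d, d),
      wp = stats::runif(d, -1, 1) / sqrt(d),
      bp = 0
    )
    if (use_prior) p <- c(p, init_knowledge_params(n, d_c, n_features))
    p$meta <- list(n_genes = G, n_proteins = n, hidden = c(h1, h2),
                   d_r = dims$d_r, d_c = dims$d_c, d_k = dims$d_k, d = d,
                   n_features = if (use_prior) as.integer(n_features) else 0L,
                   use_prior = use_prior, prelu_slope = prelu_slope)
    p
  })
}

#' Encode an RNA batch
#'
#' Two affine layers with a PReLU after each, mapping a B x G batch to the
#' B x hidden2 RNA representation.
#'
#' @param x B x G matrix.
#' @param params Model parameters (see [init_model_params()]).
#' @return B x hidden2 matrix.
#' @export
encode_rna <- function(x, params) {
  meta <- params$meta
  if (ncol(x) != meta$n_genes)
    stop_dims("gene dimension mismatch: model expects %d genes, input has %d",
              meta$n_genes, ncol(x))
  z1 <- x %*% params$W1
  z1 <- sweep(z1, 2L, params$b1, `+`)
  h1 <- prelu(z1, meta$prelu_slope)
  z2 <- h1 %*% params$W2
  z2 <- sweep(z2, 2L, params$b2, `+`)
  prelu(z2, meta$prelu_slope)
}

#' Build node matrices for a batch
#'
#' For each cell, node i is the concatenation of protein head i applied to the
#' cell's RNA representation (length `d_r`) and row i of the knowledge
#' embedding (length `d_k`).  The knowledge block is shared by every cell.
#'
#' @param rep B x hidden2 RNA representation.
#' @param params Model parameters.
#' @param vk N x d_k knowledge embedding, or `NULL` without prior knowledge.
#' @return List of B node matrices, each N x d.
#' @export
build_nodes <- function(rep, params, vk = NULL) {
  meta <- params$meta
  n <- meta$n_proteins
  if (meta$use_prior) {
    if (is.null(vk))
      stop("model was built with prior knowledge; `vk` is required",
           call. = FALSE)
    if (nrow(vk) != n || ncol(vk) != meta$d_k)
      stop_dims("knowledge embedding is %d x %d, expected %d x %d",
                nrow(vk), ncol(vk), n, meta$d_k)
  }
  lapply(seq_len(nrow(rep)), function(c) {
    vr <- t(vapply(seq_len(n), function(i)
      drop(rep[c, ] %*% params$Wh[, , i]) + params$bh[i, ],
      numeric(meta$d_r)))
    if (meta$use_prior) cbind(vr, vk) else vr
  })
}

#' One round of graph propagation
#'
#' `V^e = sigmoid(A V W)`: the trainable adjacency mixes protein nodes, the
#' relation matrix mixes feature dimensions, and an elementwise logistic maps
#' every entry into (0, 1).
#'
#' @param nodes N x d node matrix.
#' @param params Model parameters (uses `A` and `W`).
#' @return N x d matrix with entries strictly in (0, 1).
#' @export
propagate <- function(nodes, params) {
  meta <- params$meta
  if (nrow(nodes) != meta$n_proteins || ncol(nodes) != meta$d)
    stop_dims("node matrix is %d x %d, expected %d x %d",
              nrow(nodes), ncol(nodes), meta$n_proteins, meta$d)
  sigmoid(params$A %*% nodes %*% params$W)
}

#' Predict protein abundances from propagated nodes
#'
#' Shared affine map d -> 1 applied to each node row, through a PReLU so
#' negative (log-scale) abundances are reachable.
#'
#' @param nodes_e N x d propagated node matrix.
#' @param params Model parameters (uses `wp`, `bp`).
#' @return Length-N vector of predicted abundances.
#' @export
predict_nodes <- function(nodes_e, params) {
  prelu(drop(nodes_e %*% params$wp) + params$bp, params$meta$prelu_slope)
}

#' Full forward pass
#'
#' Composes [encode_rna()], the protein heads, the knowledge embedding,
#' [propagate()] and [predict_nodes()] for a batch of cells.  Cells are
#' independent: batching changes throughput only.
#'
#' @param x B x G expression batch.
#' @param params Model parameters.
#' @param priors A [prior_feature_set()] (required iff the model uses prior
#'   knowledge).
#' @return B x N matrix of predicted abundances.
#' @export
forward <- function(x, params, priors = NULL) {
  forward_pass(params, as_dense_matrix(x, "x"), priors, keep_cache = FALSE)$yhat
}

# Batched forward pass.  Exploits the structure of A V W: with
# V = [V_r | V_k], row j of A V W for cell c is
#   (sum_i A[j,i] U_i[c,]) W_r + (A V_k W_kp)[j,]
# where U_i = head_i(R) over the batch, W_r = rows 1..d_r of W and W_kp the
# remaining rows.  All per-protein quantities are kept as B x * matrices.
forward_pass <- function(params, x, priors = NULL, keep_cache = FALSE) {
  meta <- params$meta
  B <- nrow(x); n <- meta$n_proteins
  d_r <- meta$d_r; d <- meta$d
  slope <- meta$prelu_slope
  if (ncol(x) != meta$n_genes)
    stop_dims("gene dimension mismatch: model expects %d genes, input has %d",
              meta$n_genes, ncol(x))

  z1 <- sweep(x %*% params$W1, 2L, params$b1, `+`)
  h1 <- prelu(z1, slope)
  z2 <- sweep(h1 %*% params$W2, 2L, params$b2, `+`)
  rep_ <- prelu(z2, slope)

  U <- lapply(seq_len(n), function(i)
    sweep(rep_ %*% params$Wh[, , i], 2L, params$bh[i, ], `+`))

  if (meta$use_prior) {
    if (is.null(priors))
      stop("model was built with prior knowledge; `priors` is required",
           call. = FALSE)
    kc <- knowledge_embedding(priors, params, keep_cache = TRUE)
    vk <- kc$vk
    W_r <- params$W[seq_len(d_r), , drop = FALSE]
    W_kp <- params$W[d_r + seq_len(meta$d_k), , drop = FALSE]
    M_mat <- vk %*% W_kp                      # N x d
    AK <- params$A %*% M_mat                  # N x d
  } else {
    kc <- NULL; vk <- NULL; M_mat <- NULL
    W_r <- params$W
    AK <- matrix(0, n, d)
  }

  Tj <- vector("list", n); Ve <- vector("list", n)
  o <- matrix(0, B, n)
  for (j in seq_len(n)) {
    Tacc <- matrix(0, B, d_r)
    for (i in seq_len(n)) Tacc <- Tacc + params$A[j, i] * U[[i]]
    Tj[[j]] <- Tacc
    P <- Tacc %*% W_r
    P <- sweep(P, 2L, AK[j, ], `+`)
    Ve[[j]] <- sigmoid(P)
    o[, j] <- drop(Ve[[j]] %*% params$wp) + params$bp
  }
  yhat <- prelu(o, slope)
  if (!keep_cache) return(list(yhat = yhat))
  list(yhat = yhat, x = x, z1 = z1, h1 = h1, z2 = z2, rep_ = rep_, U = U,
       Tj = Tj, Ve = Ve, o = o, kc = kc, vk = vk, M_mat = M_mat,
       W_r = W_r)
}

# Mean (over cells) of the per-cell sum over proteins of squared error, and
# gradients of that loss w.r.t. every trainable array.
loss_and_grads <- function(params, x, y, priors = NULL) {
  fc <- forward_pass(params, x, priors, keep_cache = TRUE)
  meta <- params$meta
  B <- nrow(x); n <- meta$n_proteins
  d_r <- meta$d_r; d <- meta$d; slope <- meta$prelu_slope
  resid <- fc$yhat - y
  loss <- sum(resid^2) / B

  dO <- (2 / B) * resid * prelu_grad(fc$o, slope)     # B x N
  g <- list(
    W1 = matrix(0, nrow(params$W1), ncol(params$W1)),
    b1 = numeric(length(params$b1)),
    W2 = matrix(0, nrow(params$W2), ncol(params$W2)),
    b2 = numeric(length(params$b2)),
    Wh = array(0, dim(params$Wh)),
    bh = matrix(0, nrow(params$bh), ncol(params$bh)),
    A = matrix(0, n, n),
    W = matrix(0, d, d),
    wp = numeric(d),
    bp = 0
  )
  g_Wr <- matrix(0, d_r, d)
  dAK <- matrix(0, n, d)
  dU <- lapply(seq_len(n), function(i) matrix(0, B, d_r))
  for (j in seq_len(n)) {
    dOj <- dO[, j]
    g$bp <- g$bp + sum(dOj)
    g$wp <- g$wp + drop(crossprod(fc$Ve[[j]], dOj))
    dP <- (dOj %o% params$wp) * fc$Ve[[j]] * (1 - fc$Ve[[j]])
    g_Wr <- g_Wr + crossprod(fc$Tj[[j]], dP)
    dAK[j, ] <- colSums(dP)
    dT <- dP %*% t(fc$W_r)
    for (i in seq_len(n)) {
      g$A[j, i] <- g$A[j, i] + sum(dT * fc$U[[i]])
      dU[[i]] <- dU[[i]] + params$A[j, i] * dT
    }
  }

  if (meta$use_prior) {
    W_kp <- params$W[d_r + seq_len(meta$d_k), , drop = FALSE]
    g$A <- g$A + dAK %*% t(fc$M_mat)
    dM <- crossprod(params$A, dAK)                    # N x d
    g_Wkp <- crossprod(fc$vk, dM)                     # d_k x d
    dVk <- dM %*% t(W_kp)                             # N x d_k
    g$W <- rbind(g_Wr, g_Wkp)
    kg <- knowledge_backward(fc$kc, params, dVk)
    g$enc_w <- kg$enc_w; g$enc_b <- kg$enc_b
    g$Wa <- kg$Wa; g$Wk <- kg$Wk
  } else {
    g$W <- g_Wr
  }

  dR <- matrix(0, B, ncol(fc$rep_))
  for (i in seq_len(n)) {
    g$Wh[, , i] <- crossprod(fc$rep_, dU[[i]])
    g$bh[i, ] <- colSums(dU[[i]])
    dR <- dR + dU[[i]] %*% t(params$Wh[, , i])
  }
  dZ2 <- dR * prelu_grad(fc$z2, slope)
  g$W2 <- crossprod(fc$h1, dZ2)
  g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2)
  dZ1 <- dH1 * prelu_grad(fc$z1, slope)
  g$W1 <- crossprod(fc$x, dZ1)
  g$b1 <- colSums(dZ1)

  list(loss = loss, grads = g, yhat = fc$yhat)
}
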