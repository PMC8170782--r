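# Prior-knowledge embedding: M protein-protein score matrices -> one
# N x d_k matrix (d_k = N * d_c) concatenated per protein.
#
# Stages: (1) each N x N score matrix is lifted to an N x N x d_c tensor by
# per-protein 1-layer encoders; (2) the M tensors are merged with attention
# coefficients softmax-normalized across features; (3) the merged tensor is
# split into N per-protein blocks which are re-weighted by a second attention
# softmax across proteins; (4) the blocks are concatenated column-wise.

#' Initialise knowledge-embedding parameters
#'
#' Weights are drawn uniformly, scaled by the reciprocal square root of the
#' fan-in; biases start at zero.
#'
#' @param n_proteins Number of proteins N.
#' @param d_c Encoding width per protein pair (default 32).
#' @param n_features Number of prior features M.
#' @param seed Integer seed, or `NULL` to draw from the current RNG.
#' @return List with `enc_w`, `enc_b` (N x d_c scalar-to-d_c encoders, one per
#'   protein column), `Wa` (d_c x d_c x M merge weights) and `Wk`
#'   (d_c x d_c x N re-weighting weights).
#' @export
init_knowledge_params <- function(n_proteins, d_c = 32L, n_features,
                                  seed = NULL) {
  n <- as.integer(n_proteins); dc <- as.integer(d_c)
  m <- as.integer(n_features)
  stopifnot(n >= 2L, dc >= 1L, m >= 1L)
  with_seed(seed, {
    list(
      enc_w = matrix(stats::runif(n * dc, -1, 1), n, dc),
      enc_b = matrix(0, n, dc),
      Wa = array(stats::runif(dc * dc * m, -1, 1) / sqrt(dc), c(dc, dc, m)),
      Wk = array(stats::runif(dc * dc * n, -1, 1) / sqrt(dc), c(dc, dc, n))
    )
  })
}

#' Encode prior-feature matrices into high-dimensional tensors
#'
#' Column j of each N x N score matrix is encoded entry-wise by protein j's
#' 1-layer affine network (scalar in, `d_c` out), producing one N x N x d_c
#' tensor per feature.  The N encoders are shared across the M features.
#'
#' @param priors A [prior_feature_set()].
#' @param params Knowledge parameters from [init_knowledge_params()] (only
#'   `enc_w`/`enc_b` are used).
#' @return List of M arrays, each N x N x d_c.
#' @export
encode_features <- function(priors, params) {
  mats <- priors$features
  n <- length(priors$protein_ids)
  if (nrow(params$enc_w) != n)
    stop_dims("encoder parameters are for %d proteins, priors have %d",
              nrow(params$enc_w), n)
  dc <- ncol(params$enc_w)
  lapply(mats, function(C) {
    a <- array(0, c(n, n, dc))
    for (j in seq_len(n)) {
      a[, j, ] <- outer(C[, j], params$enc_w[j, ]) +
        matrix(params$enc_b[j, ], n, dc, byrow = TRUE)
    }
    a
  })
}

# scalar importance summary of one encoded tensor / block
feature_summary <- function(a) mean(elu(a))

#' Merge encoded prior features with attention
#'
#' Computes one scalar importance per feature (the mean of the
#' elu-transformed tensor), softmax-normalizes across the M features, applies
#' the per-feature d_c x d_c weight along the encoding axis, averages with
#' weight 1/M and applies a final elu.
#'
#' @param encoded List of M arrays N x N x d_c from [encode_features()].
#' @param Wa d_c x d_c x M weight array.
#' @return List with `tensor` (N x N x d_c) and `coefficients` (length-M
#'   attention weights summing to 1).
#' @export
attention_merge <- function(encoded, Wa) {
  m <- length(encoded)
  if (m == 0L) stop("need at least one encoded feature", call. = FALSE)
  d <- dim(encoded[[1L]])
  for (a in encoded)
    if (!identical(dim(a), d))
      stop_dims("encoded features disagree in shape")
  if (!identical(dim(Wa)[1:2], d[c(3L, 3L)]) || dim(Wa)[3L] != m)
    stop_dims("Wa must be %d x %d x %d", d[3L], d[3L], m)
  s <- vapply(encoded, feature_summary, numeric(1), USE.NAMES = FALSE)
  coef <- unname(softmax(s))
  nn <- d[1L] * d[2L]
  acc <- matrix(0, nn, d[3L])
  for (i in seq_len(m)) {
    acc <- acc + coef[i] * (matrix(encoded[[i]], nn, d[3L]) %*% Wa[, , i])
  }
  pre <- acc / m
  list(tensor = array(elu(pre), d),
       coefficients = coef)
}

#' Re-weight merged knowledge per protein
#'
#' Splits the merged tensor into N blocks (block j = the N x d_c slice for
#' protein column j), computes a second softmax attention across the N
#' blocks from their mean-elu summaries, and applies each block's d_c x d_c
#' weight, scalar coefficient and an elu.
#'
#' @param merged N x N x d_c array (the `tensor` from [attention_merge()]).
#' @param Wk d_c x d_c x N weight array.
#' @return List with `blocks` (list of N matrices N x d_c) and
#'   `coefficients` (length-N attention weights summing to 1).
#' @export
reweight_per_protein <- function(merged, Wk) {
  d <- dim(merged)
  n <- d[2L]; dc <- d[3L]
  if (!identical(dim(Wk), c(dc, dc, n)))
    stop_dims("Wk must be %d x %d x %d", dc, dc, n)
  blocks_in <- lapply(seq_len(n), function(j) merged[, j, , drop = TRUE])
  t_s <- vapply(blocks_in, feature_summary, numeric(1))
  coef <- softmax(t_s)
  blocks <- lapply(seq_len(n), function(j) {
    elu(coef[j] * (matrix(blocks_in[[j]], d[1L], dc) %*% Wk[, , j]))
  })
  list(blocks = blocks, coefficients = coef)
}

#' Concatenate re-weighted blocks into the knowledge embedding
#'
#' Row i of the result is the concatenation of row i of every block, giving
#' an N x (N * d_c) matrix: each protein's embedding summarises its scored
#' relations to all proteins under every protein-specific re-weighting.
#'
#' @param blocks List of N matrices, each N x d_c.
#' @return N x (N * d_c) matrix.
#' @export
concat_embedding <- function(blocks) {
  n <- length(blocks)
  d <- dim(blocks[[1L]])
  for (b in blocks)
    if (!identical(dim(b), d))
      stop_dims("blocks disagree in shape")
  if (d[1L] != n)
    stop_dims("expected %d blocks of %d rows", d[1L], d[1L])
  do.call(cbind, blocks)
}

#' Full prior-knowledge embedding
#'
#' Composes [encode_features()], [attention_merge()],
#' [reweight_per_protein()] and [concat_embedding()].
#'
#' @inheritParams encode_features
#' @param keep_cache Keep intermediates (used internally for gradients).
#' @return With `keep_cache = FALSE`, the N x d_k embedding matrix;
#'   otherwise a list `vk` + cached intermediates.
#' @export
knowledge_embedding <- function(priors, params, keep_cache = FALSE) {
  n <- length(priors$protein_ids)
  dc <- ncol(params$enc_w)
  mats <- priors$features
  m <- length(mats)
  nn <- n * n

  # encode (flat N^2 x d_c form used throughout; array form only for slicing)
  enc_flat <- vector("list", m)
  for (i in seq_len(m)) {
    C <- mats[[i]]
    a <- matrix(0, nn, dc)
    for (j in seq_len(n)) {
      rows <- (j - 1L) * n + seq_len(n)
      a[rows, ] <- outer(C[, j], params$enc_w[j, ]) +
        matrix(params$enc_b[j, ], n, dc, byrow = TRUE)
    }
    enc_flat[[i]] <- a
  }

  s <- vapply(enc_flat, function(a) mean(elu(a)), numeric(1))
  a_c <- softmax(s)
  Bi <- vector("list", m)
  acc <- matrix(0, nn, dc)
  for (i in seq_len(m)) {
    Bi[[i]] <- enc_flat[[i]] %*% params$Wa[, , i]
    acc <- acc + a_c[i] * Bi[[i]]
  }
  S_pre <- acc / m
  Ac <- elu(S_pre)                       # N^2 x d_c, column-block j = protein j

  Q <- lapply(seq_len(n), function(j) Ac[(j - 1L) * n + seq_len(n), , drop = FALSE])
  t_s <- vapply(Q, function(q) mean(elu(q)), numeric(1))
  a_k <- softmax(t_s)
  QW <- vector("list", n); Gpre <- vector("list", n); blocks <- vector("list", n)
  for (j in seq_len(n)) {
    QW[[j]] <- Q[[j]] %*% params$Wk[, , j]
    Gpre[[j]] <- a_k[j] * QW[[j]]
    blocks[[j]] <- elu(Gpre[[j]])
  }
  vk <- do.call(cbind, blocks)
  if (!keep_cache) return(vk)
  list(vk = vk, enc_flat = enc_flat, s = s, a_c = a_c, Bi = Bi,
       S_pre = S_pre, Ac = Ac, Q = Q, t_s = t_s, a_k = a_k,
       QW = QW, Gpre = Gpre, blocks = blocks, mats = mats,
       n = n, dc = dc, m = m)
}

# gradient of the knowledge embedding: dVk (N x d_k) -> parameter grads
knowledge_backward <- function(kc, params, dVk) {
  n <- kc$n; dc <- kc$dc; m <- kc$m; nn <- n * n
  g_Wk <- array(0, dim(params$Wk))
  dQ <- vector("list", n)
  dak <- numeric(n)
  for (j in seq_len(n)) {
    idx <- (j - 1L) * dc + seq_len(dc)
    dBlk <- dVk[, idx, drop = FALSE] * elu_grad(kc$Gpre[[j]])
    dak[j] <- sum(dBlk * kc$QW[[j]])
    g_Wk[, , j] <- kc$a_k[j] * crossprod(kc$Q[[j]], dBlk)
    dQ[[j]] <- kc$a_k[j] * dBlk %*% t(params$Wk[, , j])
  }
  dt <- kc$a_k * (dak - sum(kc$a_k * dak))
  for (j in seq_len(n)) {
    dQ[[j]] <- dQ[[j]] + dt[j] * elu_grad(kc$Q[[j]]) / (n * dc)
  }
  dAc <- matrix(0, nn, dc)
  for (j in seq_len(n)) dAc[(j - 1L) * n + seq_len(n), ] <- dQ[[j]]
  dS <- dAc * elu_grad(kc$S_pre)

  g_Wa <- array(0, dim(params$Wa))
  da <- numeric(m)
  dEnc <- vector("list", m)
  for (i in seq_len(m)) {
    da[i] <- sum(dS * kc$Bi[[i]]) / m
    dBi <- (kc$a_c[i] / m) * dS
    g_Wa[, , i] <- crossprod(kc$enc_flat[[i]], dBi)
    dEnc[[i]] <- dBi %*% t(params$Wa[, , i])
  }
  ds <- kc$a_c * (da - sum(kc$a_c * da))
  g_enc_w <- matrix(0, n, dc)
  g_enc_b <- matrix(0, n, dc)
  for (i in seq_len(m)) {
    dE <- dEnc[[i]] + ds[i] * elu_grad(kc$enc_flat[[i]]) / (nn * dc)
    C <- kc$mats[[i]]
    for (j in seq_len(n)) {
      rows <- (j - 1L) * n + seq_len(n)
      g_enc_w[j, ] <- g_enc_w[j, ] + crossprod(dE[rows, , drop = FALSE], C[, j])
      g_enc_b[j, ] <- g_enc_b[j, ] + colSums(dE[rows, , drop = FALSE])
    }
  }
  list(enc_w = g_enc_w, enc_b = g_enc_b, Wa = g_Wa, Wk = g_Wk)
}
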