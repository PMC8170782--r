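# Shared fixtures: tiny random inputs and an independent straight-line
# transcription of the model equations used as an oracle.

tiny_priors <- function(n = 3L, m = 2L, seed = 1L) {
  set.seed(seed)
  mats <- lapply(seq_len(m), function(i) {
    x <- matrix(runif(n * n), n, n)
    x <- (x + t(x)) / 2
    diag(x) <- 0
    x
  })
  names(mats) <- paste0("f", seq_len(m))
  prior_feature_set(mats, paste0("P", seq_len(n)))
}

tiny_model <- function(G = 6L, n = 3L, m = 2L, hidden = c(5L, 4L),
                       d_r = 2L, d_c = 2L, seed = 7L) {
  init_model_params(G, n, m, hidden = hidden, d_r = d_r, d_c = d_c,
                    seed = seed)
}

# Literal, independent transcription of the forward computation:
# knowledge embedding entirely with scalar loops; encoder/graph with plain
# matrix algebra written out step by step.  Kept free of any package
# internals beyond the parameter arrays themselves.
oracle_forward <- function(p, X, priors) {
  meta <- p$meta
  N <- meta$n_proteins; dc <- meta$d_c; dr <- meta$d_r
  M <- meta$n_features
  elu0 <- function(v) ifelse(v >= 0, v, exp(v) - 1)
  prelu0 <- function(v) ifelse(v >= 0, v, 0.25 * v)

  # encode each prior matrix: entry (k, j) -> d_c values from network j
  Aci <- vector("list", M)
  for (i in seq_len(M)) {
    Cm <- priors$features[[i]]
    a <- array(0, c(N, N, dc))
    for (k in 1:N) for (j in 1:N) for (l in 1:dc)
      a[k, j, l] <- Cm[k, j] * p$enc_w[j, l] + p$enc_b[j, l]
    Aci[[i]] <- a
  }
  # attention over features: softmax of mean-elu summaries
  s <- sapply(Aci, function(a) mean(elu0(a)))
  a_c <- exp(s) / sum(exp(s))
  S <- array(0, c(N, N, dc))
  for (i in seq_len(M)) {
    Bi <- array(0, c(N, N, dc))
    for (k in 1:N) for (j in 1:N) for (l in 1:dc)
      Bi[k, j, l] <- sum(Aci[[i]][k, j, ] * p$Wa[, l, i])
    S <- S + a_c[i] * Bi
  }
  S <- S / M
  Ac <- elu0(S)
  # per-protein re-weighting: second softmax across the N column blocks
  t_s <- sapply(1:N, function(j) mean(elu0(Ac[, j, ])))
  a_k <- exp(t_s) / sum(exp(t_s))
  Vk <- matrix(0, N, N * dc)
  for (j in 1:N) {
    Qj <- matrix(Ac[, j, ], N, dc)
    Akj <- matrix(0, N, dc)
    for (k in 1:N) for (l in 1:dc)
      Akj[k, l] <- elu0(a_k[j] * sum(Qj[k, ] * p$Wk[, l, j]))
    Vk[, (j - 1) * dc + 1:dc] <- Akj
  }

  # per cell: encoder, heads, node concat, one propagation, predictor
  B <- nrow(X)
  yhat <- matrix(0, B, N)
  for (c in seq_len(B)) {
    h1 <- prelu0(drop(X[c, ] %*% p$W1) + p$b1)
    r <- prelu0(drop(h1 %*% p$W2) + p$b2)
    V <- matrix(0, N, meta$d)
    for (i in 1:N)
      V[i, ] <- c(drop(r %*% p$Wh[, , i]) + p$bh[i, ], Vk[i, ])
    Ve <- 1 / (1 + exp(-(p$A %*% V %*% p$W)))
    for (i in 1:N)
      yhat[c, i] <- prelu0(sum(Ve[i, ] * p$wp) + p$bp)
  }
  yhat
}

# brute-force per-cell QC scan used as the oracle for qc_filter
brute_force_qc <- function(expr, mito_ids, max_rate = 0.20, min_genes = 250) {
  keep <- character(0)
  for (cell in rownames(expr)) {
    v <- expr[cell, ]
    tot <- sum(v)
    rate <- if (tot > 0) sum(v[mito_ids]) / tot else 0
    if (rate >= max_rate) next
    if (sum(v > 0) <= min_genes) next
    keep <- c(keep, cell)
  }
  keep
}
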