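test_that("encoded features have shape N x N x d_c per prior feature", {
  pr <- tiny_priors(n = 13, m = 5, seed = 2)
  kp <- init_knowledge_params(13, d_c = 32, n_features = 5, seed = 3)
  enc <- encode_features(pr, kp)
  expect_length(enc, 5)
  for (a in enc) expect_equal(dim(a), c(13L, 13L, 32L))
})

test_that("encoding is affine and maps zero priors with zero bias to zero", {
  n <- 4; m <- 2
  kp <- init_knowledge_params(n, d_c = 3, n_features = m, seed = 5)
  zero <- prior_feature_set(replicate(m, matrix(0, n, n), simplify = FALSE),
                            paste0("P", 1:n))
  enc0 <- encode_features(zero, kp)   # bias-only response
  kp0 <- kp; kp0$enc_b[] <- 0
  for (a in encode_features(zero, kp0)) expect_equal(a, array(0, c(n, n, 3)))
  pr <- tiny_priors(n, m, seed = 6)
  alpha <- 1.7
  scaled <- pr
  scaled$features <- lapply(pr$features, function(x) alpha * x)
  enc1 <- encode_features(pr, kp)
  enc2 <- encode_features(scaled, kp)
  for (i in seq_len(m))
    expect_equal(enc2[[i]], alpha * enc1[[i]] + (1 - alpha) * enc0[[i]])
})

test_that("hand-computed one-layer encoding on a known 2x2 matrix", {
  kp <- list(enc_w = matrix(c(2, -1), 2, 1),      # d_c = 1
             enc_b = matrix(c(0.5, 0.25), 2, 1))
  pr <- prior_feature_set(list(f = matrix(c(0, 3, 3, 0), 2)), c("P1", "P2"))
  enc <- encode_features(pr, kp)[[1]]
  # entry (k, j): C[k, j] * w_j + b_j
  expect_equal(enc[, , 1], matrix(c(0 * 2 + 0.5, 3 * 2 + 0.5,
                                    3 * -1 + 0.25, 0 * -1 + 0.25), 2))
})

test_that("merge attention collapses correctly for M = 1 and equal features", {
  n <- 3; dc <- 2
  kp <- init_knowledge_params(n, dc, n_features = 1, seed = 9)
  pr <- tiny_priors(n, 1, seed = 10)
  enc <- encode_features(pr, kp)
  mg <- attention_merge(enc, kp$Wa)
  expect_equal(mg$coefficients, 1)
  manual <- elu(array(matrix(enc[[1]], n * n, dc) %*% kp$Wa[, , 1],
                      c(n, n, dc)))
  expect_equal(mg$tensor, manual)

  kp2 <- init_knowledge_params(n, dc, n_features = 2, seed = 9)
  mg2 <- attention_merge(list(enc[[1]], enc[[1]]), kp2$Wa)
  expect_equal(mg2$coefficients, c(0.5, 0.5))
})

test_that("both attention coefficient vectors are simplex-valued", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:6, 1); m <- sample(1:5, 1); dc <- sample(1:4, 1)
    kp <- init_knowledge_params(n, dc, m)
    pr <- tiny_priors(n, m, seed = seed + 100)
    mg <- attention_merge(encode_features(pr, kp), kp$Wa)
    expect_true(all(mg$coefficients >= 0))
    expect_equal(sum(mg$coefficients), 1)
    rw <- reweight_per_protein(mg$tensor, kp$Wk)
    expect_true(all(rw$coefficients >= 0))
    expect_equal(sum(rw$coefficients), 1)
    expect_length(rw$blocks, n)
  }
})

test_that("re-weighting gives uniform coefficients for identical blocks", {
  n <- 4; dc <- 3
  kp <- init_knowledge_params(n, dc, 1, seed = 2)
  merged <- array(rep(0.3, n * n * dc), c(n, n, dc))  # every block equal
  rw <- reweight_per_protein(merged, kp$Wk)
  expect_equal(rw$coefficients, rep(1 / n, n))
})

test_that("concatenation lays blocks out row-wise per protein", {
  blocks <- list(matrix(c(1, 2), 2, 1), matrix(c(3, 4), 2, 1))
  vk <- concat_embedding(blocks)
  expect_equal(unname(vk), matrix(c(1, 2, 3, 4), 2))
  expect_equal(vk[1, ], c(1, 3))
  expect_equal(vk[2, ], c(2, 4))
  expect_error(concat_embedding(list(matrix(0, 2, 1))), "blocks")
})

test_that("knowledge embedding widths follow d_k = N * d_c", {
  expect_equal(model_dims(10)$d_k, 320)
  expect_equal(model_dims(13)$d_k, 416)
  pr <- tiny_priors(13, 5, seed = 3)
  kp <- init_knowledge_params(13, 32, 5, seed = 4)
  expect_equal(dim(knowledge_embedding(pr, kp)), c(13L, 416L))
})

test_that("all-zero priors with zero biases leak no protein-specific signal", {
  n <- 5; dc <- 3
  kp <- init_knowledge_params(n, dc, 2, seed = 8)
  kp$enc_b[] <- 0
  zero <- prior_feature_set(replicate(2, matrix(0, n, n), simplify = FALSE),
                            paste0("P", 1:n))
  vk <- knowledge_embedding(zero, kp)
  for (i in 2:n) expect_equal(vk[i, ], vk[1, ])
})

test_that("composite embedding equals the exported stage-by-stage pipeline", {
  pr <- tiny_priors(4, 3, seed = 12)
  kp <- init_knowledge_params(4, 2, 3, seed = 13)
  vk <- knowledge_embedding(pr, kp)
  mg <- attention_merge(encode_features(pr, kp), kp$Wa)
  rw <- reweight_per_protein(mg$tensor, kp$Wk)
  expect_equal(vk, concat_embedding(rw$blocks))
})
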