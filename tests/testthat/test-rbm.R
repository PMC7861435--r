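zero_rbm <- function(nv, nh, type = "sigmoid") {
  p <- init_rbm(nv, nh, type, init_sd = 0, seed = 1)
  p  # all weights and biases exactly zero
}

test_that("conditional layer sampling follows the stated distributions", {
  # zero-parameter sigmoid model: activation probability exactly 0.5
  p <- zero_rbm(3, 4)
  h <- sample_hidden_given_visible(p, matrix(0, 4000, 3), seed = 2)
  expect_true(all(h %in% c(0, 1)))
  expect_lt(abs(mean(h) - 0.5), 0.02)

  # relu samples are non-negative and match the truncated-normal mean
  pr <- zero_rbm(1, 1, "relu")
  pr$hidden_bias <- 5
  h5 <- sample_hidden_given_visible(pr, matrix(0, 1e5, 1), seed = 3)
  expect_true(all(h5 >= 0))
  expect_lt(abs(mean(h5) - 5), 0.05)  # truncation negligible at mu = 5
  pr$hidden_bias <- 0
  h0 <- sample_hidden_given_visible(pr, matrix(0, 1e5, 1), seed = 4)
  expect_true(all(h0 >= 0))
  expect_lt(abs(mean(h0) - (dnorm(0) / pnorm(0))), 0.01)

  # visible units: sigmoid limit for a strongly negative bias
  pv <- zero_rbm(2, 2)
  pv$visible_bias <- c(-8, 0)
  v <- sample_visible_given_hidden(pv, matrix(0, 1e4, 2), seed = 5)
  expect_lt(mean(v[, 1]), 0.005)
  expect_lt(abs(mean(v[, 2]) - 0.5), 0.02)
  expect_identical(sample_visible_given_hidden(pv, matrix(0, 10, 2), seed = 6),
                   sample_visible_given_hidden(pv, matrix(0, 10, 2), seed = 6))
})

test_that("exact enumeration gradient matches finite differences", {
  p <- init_rbm(4, 2, "sigmoid", init_sd = 0.3, seed = 2)
  data <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0))
  ex <- exact_loglik_gradient(p, data)
  # independent finite-difference oracle on the enumerated log-likelihood
  loglik <- function(pp) {
    states <- haplogen:::enumerate_states(4)
    lw <- -haplogen:::rbm_free_energy(pp, states)
    lz <- max(lw) + log(sum(exp(lw - max(lw))))
    mean(-haplogen:::rbm_free_energy(pp, data) - lz)
  }
  eps <- 1e-6
  for (idx in list(c(1, 1), c(2, 1), c(4, 2))) {
    p2 <- p; p2$W[idx[1], idx[2]] <- p2$W[idx[1], idx[2]] + eps
    expect_lt(abs((loglik(p2) - loglik(p)) / eps - ex$W[idx[1], idx[2]]),
              1e-5)
  }
  p2 <- p; p2$visible_bias[3] <- p2$visible_bias[3] + eps
  expect_lt(abs((loglik(p2) - loglik(p)) / eps - ex$vb[3]), 1e-5)
  p2 <- p; p2$hidden_bias[2] <- p2$hidden_bias[2] + eps
  expect_lt(abs((loglik(p2) - loglik(p)) / eps - ex$hb[2]), 1e-5)

  # zero-parameter model on balanced data: zero visible-bias gradient
  p0 <- zero_rbm(3, 2)
  bal <- rbind(c(1, 0, 1), c(0, 1, 0))
  ex0 <- exact_loglik_gradient(p0, bal)
  expect_equal(ex0$vb, rep(0, 3), tolerance = 1e-12)
  # and the enumerated visible marginal is uniform
  expect_equal(rbm_exact_marginal(p0)$prob, rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("averaged PCD gradients converge to the exact gradient", {
  p <- init_rbm(4, 2, "sigmoid", init_sd = 0.3, seed = 2)
  data <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 0, 1, 0))
  ex <- exact_loglik_gradient(p, data)
  set.seed(7)
  mad_for_k <- vapply(c(1, 10), function(k) {
    chains <- matrix(rbinom(100 * 4, 1, 0.5), 100, 4)
    nrep <- 150
    accW <- p$W * 0; accv <- numeric(4); acch <- numeric(2)
    for (i in seq_len(nrep)) {
      g <- pcd_gradient(p, chains, data, k = k)
      chains <- g$chains
      accW <- accW + g$grad$W; accv <- accv + g$grad$vb
      acch <- acch + g$grad$hb
    }
    mean(abs(c(accW / nrep - ex$W, accv / nrep - ex$vb, acch / nrep - ex$hb)))
  }, numeric(1))
  expect_lt(mad_for_k[2], 0.01)       # PCD-10 with 100 chains is accurate
  expect_lte(mad_for_k[2], mad_for_k[1] + 0.005)  # more sweeps never worse

  # learning_rate 0 leaves parameters untouched
  ch <- matrix(rbinom(40, 1, 0.5), 10, 4)
  up <- pcd_update(p, ch, data, learning_rate = 0, k = 2)
  expect_identical(up$params$W, p$W)
})

test_that("Gibbs sampling reaches the enumerated stationary distribution", {
  p <- init_rbm(4, 2, "sigmoid", init_sd = 0.4, seed = 12)
  truth <- rbm_exact_marginal(p)
  samp <- sample_rbm(p, 20000, init = "random", n_gibbs = 60, seed = 13)
  emp <- table(factor(apply(as.matrix(samp), 1, paste, collapse = ""),
                      levels = truth$state)) / 20000
  expect_lt(sum(abs(as.numeric(emp) - truth$prob)) / 2, 0.05)
})

test_that("sampling respects initialisation schemes and the n_gibbs contract", {
  p <- zero_rbm(5, 3)
  init <- random_hap(8, 5, seed = 3)
  out <- sample_rbm(p, 8, init = "train_set", init_data = init, n_gibbs = 0,
                    seed = 4)
  expect_true(all(as.matrix(out) %in% as.matrix(init)))  # untouched rows
  expect_error(sample_rbm(p, 5, init = "train_set"), "init_data")
  # zero-parameter model: site frequencies 0.5 whatever the start
  big <- sample_rbm(p, 10000, init = "random", n_gibbs = 3, seed = 5)
  expect_lt(max(abs(allele_frequencies(big) - 0.5)), 0.03)
})

test_that("n_gibbs = 0 with train_set init returns the init rows unchanged", {
  p <- zero_rbm(6, 2)
  init <- random_hap(10, 6, seed = 8)
  out <- sample_rbm(p, 10, init = "train_set", init_data = init, n_gibbs = 0,
                    seed = 9)
  # rows are drawn (without replacement here) from init: same multiset
  expect_setequal(apply(as.matrix(out), 1, paste, collapse = ""),
                  apply(as.matrix(init), 1, paste, collapse = ""))
})

test_that("training a tiny RBM recovers a two-mode distribution", {
  modes <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  train <- haplotype_matrix(modes[rep(1:2, each = 30), ])
  fit <- suppressWarnings(  # toy-scale learning rate above the panel range
    train_rbm(train, n_hidden = 4, hidden_type = "sigmoid",
              learning_rate = 0.05, batch_size = 10, pcd_k = 5,
              n_chains = 50, epochs = 300, probe_interval = 100, seed = 5))
  samp <- as.matrix(sample_rbm(fit, 2000, init = "random", n_gibbs = 50,
                               seed = 6))
  top2 <- names(sort(table(apply(samp, 1, paste, collapse = "")),
                     decreasing = TRUE))[1:2]
  expect_setequal(top2, c("111000", "000111"))
})

test_that("sampling-set initialisation is less overfit than train-set", {
  # a deliberately memorised model (many hidden units, strong learning, tiny
  # training set): chains started on training rows stay glued to them (AA_TS
  # near 0), chains started on an independent sampling set drift less toward
  # the memorised points, so their AA_TS is higher
  M <- simulate_structured(n_pops = 2, haplotypes_per_pop = 100, n_snps = 20,
                           differentiation = 0.3, seed = 23)
  sp <- split_train_test(M, ratio = 0.2, seed = 23)    # 40 training rows
  train <- sp$train
  sampling <- split_train_test(sp$test, ratio = 0.5, seed = 24)$train
  fit <- suppressWarnings(
    train_rbm(train, n_hidden = 60, learning_rate = 0.05, batch_size = 10,
              epochs = 1500, probe_interval = 750, seed = 25))
  n <- n_haplotypes(train)
  aa_t <- mean(vapply(26:29, function(s)
    aa_ts_score(train, sample_rbm(fit, n, init = "train_set",
                                  init_data = train, n_gibbs = 3, seed = s)),
    numeric(1)))
  aa_s <- mean(vapply(26:29, function(s)
    aa_ts_score(train, sample_rbm(fit, n, init = "sampling_set",
                                  init_data = sampling, n_gibbs = 3,
                                  seed = s)), numeric(1)))
  expect_lt(aa_t, 0.5)       # both overfit in absolute terms...
  expect_gt(aa_s, aa_t)      # ...but the sampling-set start less so
})

test_that("hidden encodings and SVD axes behave as documented", {
  pr <- zero_rbm(4, 3, "relu")
  enc <- hidden_encoding(pr, random_hap(5, 4, seed = 2))
  expect_equal(dim(enc), c(5, 3))
  expect_equal(as.numeric(enc), rep(dnorm(0) / pnorm(0), 15),
               tolerance = 1e-12)

  p <- init_rbm(6, 4, seed = 3, init_sd = 0.5)
  s <- svd_axes(p)
  expect_equal(s$visible_axes %*% diag(s$singular_values) %*%
                 t(s$hidden_axes), p$W, tolerance = 1e-8)
  # rank-1 weight matrix has exactly one non-negligible singular value
  p1 <- p; p1$W <- outer(rnorm(6), rnorm(4))
  sv <- svd_axes(p1)$singular_values
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("hidden units and projections pick up population structure", {
  M <- simulate_structured(n_pops = 2, haplotypes_per_pop = 100, n_snps = 40,
                           differentiation = 0.4, seed = 17)
  fit <- train_rbm(M, n_hidden = 8, learning_rate = 1e-3, epochs = 80,
                   probe_interval = 40, seed = 18)
  enc <- hidden_encoding(fit, M)
  lab <- hap_labels(M)
  sep <- vapply(seq_len(ncol(enc)), function(j) {
    a <- enc[lab == "POP1", j]; b <- enc[lab == "POP2", j]
    abs(mean(a) - mean(b)) /
      sqrt(var(a) / length(a) + var(b) / length(b))
  }, numeric(1))
  expect_gt(max(sep), 2)  # at least one node separates the populations
  # the SVD hidden-axis projection separates better than shuffled labels
  proj <- project_hidden(fit, M, n_axes = 2)
  set.seed(19)
  expect_gt(silhouette_score(proj, lab),
            silhouette_score(proj, sample(lab)))
})
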