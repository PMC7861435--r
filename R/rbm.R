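#' Restricted Boltzmann machine for binary haplotypes
#'
#' An RBM couples a visible layer of `n_visible` Bernoulli units (one per
#' SNP, coding 0/1 alleles) to `n_hidden` latent units through a weight
#' matrix W.  The joint law is `P(v, h) = exp(-E(v, h)) / Z` with energy
#' `E(v, h) = -v' W h - a'v - b'h` (plus `sum(h^2)/2` for continuous relu
#' units), so larger `W[i, j] * v[i] * h[j]` means higher probability.
#' Hidden units are either binary with sigmoid conditionals, or rectified
#' continuous units whose conditional given v is a unit-variance Gaussian
#' truncated to the non-negative half-line.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param hidden_type `"relu"` (default, the better-performing variant) or
#'   `"sigmoid"`.
#' @param init_sd standard deviation of the Gaussian weight initialisation
#'   (biases start at 0).
#' @param seed integer seed for the initial weights.
#' @return an object of class `rbm_params`: list with `W`
#'   (`n_visible x n_hidden`), `visible_bias`, `hidden_bias`, `hidden_type`.
#' @export
init_rbm <- function(n_visible, n_hidden, hidden_type = c("relu", "sigmoid"),
                     init_sd = 0.01, seed = 1L) {
  hidden_type <- match.arg(hidden_type)
  stopifnot(n_visible >= 1L, n_hidden >= 1L)
  withr_seed(seed, {
    structure(list(
      W = matrix(stats::rnorm(n_visible * n_hidden, 0, init_sd),
                 n_visible, n_hidden),
      visible_bias = numeric(n_visible),
      hidden_bias = numeric(n_hidden),
      hidden_type = hidden_type), class = "rbm_params")
  })
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("<rbm_params: %d visible x %d hidden (%s), |W| in [%.3g, %.3g]>\n",
              nrow(x$W), ncol(x$W), x$hidden_type,
              min(x$W), max(x$W)))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# mean of N(mu, 1) truncated to [0, Inf): mu + phi(mu) / Phi(mu)
truncnorm_mean <- function(mu) {
  mu + exp(stats::dnorm(mu, log = TRUE) - stats::pnorm(mu, log.p = TRUE))
}

# draw from N(mu, 1) truncated to [0, Inf), numerically stable in both tails
rtruncnorm0 <- function(mu) {
  u <- stats::runif(length(mu))
  lp <- stats::pnorm(mu, log.p = TRUE)  # log P(N(mu,1) > 0)
  x <- mu + stats::qnorm(log1p(-u) + lp, lower.tail = FALSE, log.p = TRUE)
  x <- pmax(x, 0)
  dim(x) <- dim(mu)
  x
}

# pre-activation of the hidden layer for a visible batch (rows = cases)
hidden_input <- function(params, v) {
  sweep(v %*% params$W, 2L, params$hidden_bias, `+`)
}

# conditional mean E[h | v] (no sampling noise)
hidden_mean <- function(params, v) {
  mu <- hidden_input(params, v)
  if (params$hidden_type == "sigmoid") sigmoid(mu) else truncnorm_mean(mu)
}

#' Conditional layer sampling
#'
#' `sample_hidden_given_visible()` draws the hidden layer given a visible
#' batch: Bernoulli at the sigmoid activation for binary hidden units, or a
#' unit-variance truncated (non-negative) Gaussian centred at the
#' pre-activation for relu units.  `sample_visible_given_hidden()` draws the
#' visible layer as Bernoulli units at `sigmoid(W h + visible_bias)`.
#'
#' @param params an `rbm_params` object.
#' @param v visible batch, rows = cases, entries 0/1.
#' @param h hidden batch, rows = cases.
#' @param seed optional integer seed; `NULL` (default) uses the current RNG
#'   stream (so training consumes one seeded stream end to end).
#' @return a matrix with one row per case.
#' @export
sample_hidden_given_visible <- function(params, v, seed = NULL) {
  draw <- function() {
    mu <- hidden_input(params, v)
    if (params$hidden_type == "sigmoid") {
      h <- matrix(stats::rbinom(length(mu), 1L, sigmoid(mu)), nrow(mu), ncol(mu))
    } else {
      h <- rtruncnorm0(mu)
    }
    h
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

#' @rdname sample_hidden_given_visible
#' @export
sample_visible_given_hidden <- function(params, h, seed = NULL) {
  draw <- function() {
    p <- sigmoid(sweep(tcrossprod(h, params$W), 2L, params$visible_bias, `+`))
    matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# one alternating Gibbs sweep v -> h -> v on a visible batch
gibbs_sweep <- function(params, v) {
  h <- sample_hidden_given_visible(params, v)
  sample_visible_given_hidden(params, h)
}

# sufficient statistics <v_i h_j>, <v_i>, <h_j> with Rao-Blackwellised hidden
rbm_stats <- function(params, v) {
  hm <- hidden_mean(params, v)
  list(W = crossprod(v, hm) / nrow(v),
       vb = colMeans(v),
       hb = colMeans(hm))
}

#' Persistent contrastive divergence gradient and update
#'
#' `pcd_gradient()` estimates the log-likelihood gradient: the positive term
#' from the data batch and the negative term from persistent Gibbs chains
#' advanced `k` alternating sweeps (PCD-k).  `pcd_update()` applies one
#' gradient-ascent step and returns the updated parameters together with the
#' advanced chains, which persist across calls.
#'
#' @param params an `rbm_params` object.
#' @param chains persistent-chain visible states, `n_chains x n_visible`
#'   matrix of 0/1 entries.
#' @param batch data minibatch, rows = haplotypes.
#' @param k number of Gibbs sweeps per update (default 10).
#' @param learning_rate step size for `pcd_update`.
#' @return `pcd_gradient`: list with `grad` (list `W`, `vb`, `hb`) and
#'   `chains`; `pcd_update`: list with `params` and `chains`.
#' @export
pcd_gradient <- function(params, chains, batch, k = 10L) {
  stopifnot(ncol(chains) == nrow(params$W), ncol(batch) == nrow(params$W))
  pos <- rbm_stats(params, batch)
  for (s in seq_len(k)) chains <- gibbs_sweep(params, chains)
  neg <- rbm_stats(params, chains)
  grad <- list(W = pos$W - neg$W, vb = pos$vb - neg$vb, hb = pos$hb - neg$hb)
  if (!all(vapply(grad, function(g) all(is.finite(g)), logical(1))))
    stop("non-finite PCD gradient; training diverged", call. = FALSE)
  list(grad = grad, chains = chains)
}

#' @rdname pcd_gradient
#' @export
pcd_update <- function(params, chains, batch, learning_rate = 1e-3, k = 10L) {
  g <- pcd_gradient(params, chains, batch, k = k)
  params$W <- params$W + learning_rate * g$grad$W
  params$visible_bias <- params$visible_bias + learning_rate * g$grad$vb
  params$hidden_bias <- params$hidden_bias + learning_rate * g$grad$hb
  list(params = params, chains = g$chains)
}

# free energy F(v) = -log sum_h / int_h exp(-E(v, h)), up to constants
rbm_free_energy <- function(params, v) {
  mu <- hidden_input(params, v)
  hidden_term <- if (params$hidden_type == "sigmoid") {
    rowSums(log1p(exp(mu)))
  } else {
    # int_0^inf exp(mu*h - h^2/2) dh = exp(mu^2/2) sqrt(2 pi) Phi(mu)
    rowSums(mu^2 / 2 + stats::pnorm(mu, log.p = TRUE) + 0.5 * log(2 * pi))
  }
  -(v %*% params$visible_bias)[, 1L] - hidden_term
}

# all binary states of length n as a (2^n x n) matrix, row-major count order
enumerate_states <- function(n) {
  stopifnot(n <= 20L)
  m <- matrix(0L, 2L^n, n)
  for (j in seq_len(n)) m[, j] <- rep(rep(0:1, each = 2L^(n - j)), 2L^(j - 1L))
  m
}

#' Exact RBM likelihood quantities by enumeration (small models only)
#'
#' `rbm_exact_marginal()` enumerates all visible configurations and returns
#' the exact marginal `P(v)`; `exact_loglik_gradient()` returns the exact
#' gradient of the mean log-likelihood of `data`, both obtained by analytic
#' marginalisation of the hidden layer.  Feasible only for small layers;
#' intended as the independent oracle against which stochastic PCD training
#' is checked.
#'
#' @param params an `rbm_params` object with `n_visible <= 20`.
#' @param data visible data matrix (rows = cases, 0/1 entries).
#' @return `rbm_exact_marginal`: tibble with columns `state` (binary string)
#'   and `prob`; `exact_loglik_gradient`: list `W`, `vb`, `hb`.
#' @export
rbm_exact_marginal <- function(params) {
  nv <- nrow(params$W)
  if (nv > 20L) stop("enumeration limited to n_visible <= 20", call. = FALSE)
  states <- enumerate_states(nv)
  logw <- -rbm_free_energy(params, states)
  logw <- logw - max(logw)
  p <- exp(logw) / sum(exp(logw))
  tibble::tibble(state = apply(states, 1L, paste, collapse = ""), prob = p)
}

#' @rdname rbm_exact_marginal
#' @export
exact_loglik_gradient <- function(params, data) {
  nv <- nrow(params$W)
  if (nv > 20L) stop("enumeration limited to n_visible <= 20", call. = FALSE)
  data <- as.matrix(data)
  states <- enumerate_states(nv)
  logw <- -rbm_free_energy(params, states)
  logw <- logw - max(logw)
  p <- exp(logw) / sum(exp(logw))
  hm_states <- hidden_mean(params, states)
  model <- list(W = crossprod(states * p, hm_states),
                vb = colSums(states * p),
                hb = colSums(hm_states * p))
  dat <- rbm_stats(params, data)
  list(W = dat$W - model$W, vb = dat$vb - model$vb, hb = dat$hb - model$hb)
}

#' Train an RBM on haplotype data with PCD-k
#'
#' Minibatch persistent-contrastive-divergence training (k Gibbs sweeps per
#' update, a fixed pool of persistent chains).  Optionally, a held-out probe
#' set is scored at fixed epoch intervals with the nearest-neighbour
#' adversarial accuracy between freshly sampled artificial haplotypes and the
#' probe; training can stop early once the probe converges to the ideal 0.5.
#'
#' @param M training [haplotype_matrix()].
#' @param n_hidden number of hidden units (reference choices: 100 for an
#'   805-SNP panel, 500 for a 10K panel).
#' @param hidden_type `"relu"` (default) or `"sigmoid"`.
#' @param learning_rate step size; the stable range is 1e-4 to 1e-3
#'   (values outside it are accepted with a warning).
#' @param batch_size minibatch size (default 32).
#' @param pcd_k Gibbs sweeps per update (default 10).
#' @param n_chains persistent chains (default 100).
#' @param epochs maximum training epochs.
#' @param probe optional held-out [haplotype_matrix()] scored during training.
#' @param probe_interval epochs between probe evaluations.
#' @param probe_gibbs Gibbs sweeps used to sample the probe's artificial set.
#' @param stop_at_aats if `TRUE`, stop when the probe AA_TS is within
#'   `aats_tol` of 0.5 for two consecutive probes.
#' @param aats_tol convergence half-width for `stop_at_aats` (default 0.05).
#' @param seed integer seed governing all training randomness.
#' @return an object of class `rbm_fit`: list with `params` (`rbm_params`),
#'   `history` (tibble: epoch, mean reconstruction error, probe AA_TS when
#'   probed) and the configuration used.
#' @export
train_rbm <- function(M, n_hidden = 100L, hidden_type = c("relu", "sigmoid"),
                      learning_rate = 1e-3, batch_size = 32L, pcd_k = 10L,
                      n_chains = 100L, epochs = 300L, probe = NULL,
                      probe_interval = 20L, probe_gibbs = 50L,
                      stop_at_aats = FALSE, aats_tol = 0.05, seed = 1L) {
  M <- validate_haplotype_matrix(M)
  hidden_type <- match.arg(hidden_type)
  if (learning_rate > 1e-3 || learning_rate < 1e-4)
    warning("learning_rate outside the reference range [1e-4, 1e-3]")
  v <- hap_values(M)
  n <- nrow(v); nv <- ncol(v)
  if (batch_size > n) stop("batch size exceeds number of haplotypes",
                           call. = FALSE)
  params <- init_rbm(nv, n_hidden, hidden_type, seed = seed)
  hist_epoch <- integer(0); hist_err <- numeric(0); hist_aats <- numeric(0)
  withr_seed(seed + 1L, {
    chains <- matrix(stats::rbinom(n_chains * nv, 1L, 0.5), n_chains, nv)
    prev_ok <- FALSE
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n - batch_size + 1L, by = batch_size)
      for (s in starts) {
        batch <- v[idx[s:(s + batch_size - 1L)], , drop = FALSE]
        up <- pcd_update(params, chains, batch, learning_rate, k = pcd_k)
        params <- up$params; chains <- up$chains
      }
      aats_now <- NA_real_
      if (ep %% probe_interval == 0L || ep == epochs) {
        recon <- sample_visible_given_hidden(
          params, hidden_mean(params, v[idx[seq_len(min(n, 200L))], ,
                                        drop = FALSE]))
        err <- mean(recon != v[idx[seq_len(min(n, 200L))], , drop = FALSE])
        if (!is.null(probe)) {
          ag <- rbm_gibbs_matrix(params, n_haplotypes(probe),
                                 init = "random", init_data = NULL,
                                 n_gibbs = probe_gibbs)
          aats_now <- adversarial_accuracy(
            nearest_neighbor_profile(probe, haplotype_matrix(ag)))$aa_ts
        }
        hist_epoch <- c(hist_epoch, ep)
        hist_err <- c(hist_err, err)
        hist_aats <- c(hist_aats, aats_now)
        if (stop_at_aats && !is.na(aats_now)) {
          ok <- abs(aats_now - 0.5) < aats_tol
          if (ok && prev_ok) break
          prev_ok <- ok
        }
      }
    }
  })
  structure(list(params = params,
                 history = tibble::tibble(epoch = hist_epoch,
                                          recon_error = hist_err,
                                          aats_probe = hist_aats),
                 config = list(n_hidden = n_hidden, hidden_type = hidden_type,
                               learning_rate = learning_rate,
                               batch_size = batch_size, pcd_k = pcd_k,
                               n_chains = n_chains, epochs = epochs,
                               seed = seed)),
            class = "rbm_fit")
}

#' @export
print.rbm_fit <- function(x, ...) {
  cat(sprintf("<rbm_fit: %d visible x %d hidden (%s), %d epochs trained>\n",
              nrow(x$params$W), ncol(x$params$W), x$params$hidden_type,
              max(c(0L, x$history$epoch))))
  invisible(x)
}

# raw Gibbs sampling returning a plain visible matrix (internal)
rbm_gibbs_matrix <- function(params, n, init, init_data, n_gibbs) {
  nv <- nrow(params$W)
  v <- switch(init,
    random = matrix(stats::rbinom(n * nv, 1L, 0.5), n, nv),
    train_set = ,
    sampling_set = {
      if (is.null(init_data))
        stop("init_data is required for ", init, " initialisation",
             call. = FALSE)
      dv <- hap_values(init_data)
      dv[sample.int(nrow(dv), n, replace = n > nrow(dv)), , drop = FALSE]
    },
    stop("unknown init scheme: ", init, call. = FALSE))
  if (n_gibbs > 0) for (s in seq_len(n_gibbs)) v <- gibbs_sweep(params, v)
  v
}

#' Sample artificial haplotypes from a trained RBM
#'
#' Runs `n` parallel Gibbs chains for `n_gibbs` alternating sweeps and
#' returns the final visible states.  Chains start either from random 0/1
#' noise, from rows of the training set, or from rows of an independent
#' "sampling set" — the latter reduces the overfitting that training-set
#' initialisation inherits when the model memorises training points.
#'
#' @param params an `rbm_params` object (or an `rbm_fit`, whose params are
#'   used).
#' @param n number of haplotypes to sample.
#' @param init chain initialisation scheme: `"random"`, `"train_set"` or
#'   `"sampling_set"`.
#' @param init_data [haplotype_matrix()] whose rows seed the chains; required
#'   for the `train_set` and `sampling_set` schemes.
#' @param n_gibbs alternating Gibbs sweeps to run (default 100).
#' @param seed integer seed.
#' @return a [haplotype_matrix()] of `n` sampled haplotypes.
#' @export
sample_rbm <- function(params, n, init = c("random", "train_set",
                                           "sampling_set"),
                       init_data = NULL, n_gibbs = 100L, seed = 1L) {
  if (inherits(params, "rbm_fit")) params <- params$params
  init <- match.arg(init)
  stopifnot(n >= 1L)
  withr_seed(seed, {
    haplotype_matrix(rbm_gibbs_matrix(params, n, init, init_data, n_gibbs))
  })
}

#' Hidden-layer encoding of haplotypes
#'
#' Deterministic latent representation: the conditional mean activation of
#' every hidden unit given each haplotype (sigmoid probability for binary
#' hidden units, truncated-Gaussian mean for relu units; no sampling noise).
#' Different populations typically activate different hidden nodes, so the
#' table doubles as a non-linear data encoding.
#'
#' @param params an `rbm_params` or `rbm_fit`.
#' @param M a [haplotype_matrix()].
#' @return numeric matrix, `n_haplotypes x n_hidden`.
#' @export
hidden_encoding <- function(params, M) {
  if (inherits(params, "rbm_fit")) params <- params$params
  hidden_mean(params, hap_values(M))
}

#' SVD axes of the RBM weight matrix
#'
#' The singular value decomposition `W = U diag(d) V'` yields two coordinate
#' systems: the columns of U live in visible (SNP) space ("visible axes",
#' comparable to principal component axes) and the columns of V in the hidden
#' representation ("hidden axes").  `project_hidden()` maps haplotypes onto
#' the top hidden axes — coordinates `v W V = v U diag(d)` — the package's
#' non-linear-model-based dimension reduction.
#'
#' @param params an `rbm_params` or `rbm_fit`.
#' @return list with `visible_axes` (U), `hidden_axes` (V), `singular_values`.
#' @export
svd_axes <- function(params) {
  if (inherits(params, "rbm_fit")) params <- params$params
  s <- svd(params$W)
  list(visible_axes = s$u, hidden_axes = s$v, singular_values = s$d)
}

#' @rdname svd_axes
#' @param M a [haplotype_matrix()] to project.
#' @param n_axes number of leading hidden axes to keep.
#' @return `project_hidden`: numeric matrix `n_haplotypes x n_axes`.
#' @export
project_hidden <- function(params, M, n_axes = 2L) {
  if (inherits(params, "rbm_fit")) params <- params$params
  s <- svd(params$W)
  n_axes <- min(n_axes, length(s$d))
  (hap_values(M) %*% s$u[, seq_len(n_axes), drop = FALSE]) %*%
    diag(s$d[seq_len(n_axes)], n_axes)
}
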