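#' GAN layer-size rules
#'
#' The generator stacks dense layers `latent -> round(n_snps/1.2) ->
#' round(n_snps/1.1) -> n_snps`; the discriminator `n_snps ->
#' round(n_snps/2) -> round(n_snps/3) -> 1`.  Rounding is half-away-from-zero
#' (805/2 = 402.5 -> 403), which differs from R's banker's rounding by at
#' most one unit.
#'
#' @param n_snps number of SNPs (>= 4; smaller panels make the hidden sizes
#'   degenerate).
#' @return list with integer vectors `gen_hidden` (2) and `disc_hidden` (2).
#' @examples
#' gan_layer_sizes(805)   # gen 671/732, disc 403/268
#' @export
gan_layer_sizes <- function(n_snps) {
  if (n_snps < 4L) stop("n_snps must be at least 4", call. = FALSE)
  r <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))
  list(gen_hidden = c(r(n_snps / 1.2), r(n_snps / 1.1)),
       disc_hidden = c(r(n_snps / 2), r(n_snps / 3)))
}

#' GAN configuration
#'
#' Collects the hyperparameters of the fully-connected GAN: latent dimension
#' 600, hidden sizes from [gan_layer_sizes()], LeakyReLU slope 0.01 with L2
#' penalty 1e-4 on hidden weights, Adam with discriminator learning rate
#' 8e-4 and combined-model (generator) learning rate 1e-4, batch size 32,
#' real-label smoothing drawn uniformly from \[0.9, 1\], a 3:1
#' training:validation split, and an adversarial-accuracy probe every 200
#' epochs.  `large_panel = TRUE` selects the tenfold-lower learning rates
#' used for dense multi-thousand-SNP panels.
#'
#' @param n_snps number of SNPs the model generates.
#' @param latent_dim latent vector size (default 600).
#' @param leaky_alpha LeakyReLU negative slope.
#' @param l2 L2 penalty on hidden-layer weights.
#' @param lr_disc,lr_gan Adam learning rates (discriminator / combined model).
#' @param large_panel use the lowered learning rates 8e-5 / 1e-5.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param smoothing_upper real labels are `1 - U(0, smoothing_upper)`,
#'   i.e. smoothed into \[1 - smoothing_upper, 1\].
#' @param probe_interval epochs between AA_TS probe evaluations.
#' @param train_fraction training share of the input data (default 3:1).
#' @param rescale if `TRUE`, data are mapped to \[-1, 1\] to match the tanh
#'   output and generated values are thresholded at 0; if `FALSE` (default)
#'   data stay 0/1 and generated values are thresholded at 0.5.
#' @return list of class `gan_config`.
#' @export
gan_config <- function(n_snps, latent_dim = 600L, leaky_alpha = 0.01,
                       l2 = 1e-4, lr_disc = 8e-4, lr_gan = 1e-4,
                       large_panel = FALSE, batch_size = 32L, epochs = 2000L,
                       smoothing_upper = 0.1, probe_interval = 200L,
                       train_fraction = 0.75, rescale = FALSE) {
  stopifnot(latent_dim >= 1L, batch_size >= 1L, epochs >= 1L,
            lr_disc > 0, lr_gan > 0,
            smoothing_upper >= 0, smoothing_upper <= 1)
  if (large_panel) { lr_disc <- 8e-5; lr_gan <- 1e-5 }
  sizes <- gan_layer_sizes(n_snps)
  structure(list(n_snps = as.integer(n_snps), latent_dim = as.integer(latent_dim),
                 gen_hidden = sizes$gen_hidden, disc_hidden = sizes$disc_hidden,
                 leaky_alpha = leaky_alpha, l2 = l2,
                 lr_disc = lr_disc, lr_gan = lr_gan,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 smoothing_upper = smoothing_upper,
                 probe_interval = as.integer(probe_interval),
                 train_fraction = train_fraction, rescale = isTRUE(rescale)),
            class = "gan_config")
}

## --- minimal dense-network machinery (Glorot init, LeakyReLU/tanh, Adam) ---

glorot_layer <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

mlp_new <- function(sizes, act) {
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) layers[[i]] <- glorot_layer(sizes[i], sizes[i + 1L])
  list(layers = layers, act = act)
}

act_fwd <- function(x, kind, alpha) {
  switch(kind,
         lrelu = ifelse(x > 0, x, alpha * x),
         tanh = tanh(x),
         linear = x)
}

act_grad <- function(pre, post, kind, alpha) {
  switch(kind,
         lrelu = ifelse(pre > 0, 1, alpha),
         tanh = 1 - post^2,
         linear = 1)
}

mlp_forward <- function(net, x, alpha) {
  pre <- post <- vector("list", length(net$layers))
  a <- x
  for (i in seq_along(net$layers)) {
    z <- sweep(a %*% net$layers[[i]]$W, 2L, net$layers[[i]]$b, `+`)
    pre[[i]] <- z
    a <- act_fwd(z, net$act[i], alpha)
    post[[i]] <- a
  }
  list(out = a, pre = pre, post = post, input = x)
}

# backprop dL/d(output) through the net; returns weight grads and dL/d(input)
mlp_backward <- function(net, cache, dout, alpha, l2 = 0) {
  n <- length(net$layers)
  grads <- vector("list", n)
  delta <- dout
  for (i in rev(seq_len(n))) {
    delta <- delta * act_grad(cache$pre[[i]], cache$post[[i]], net$act[i], alpha)
    a_prev <- if (i == 1L) cache$input else cache$post[[i - 1L]]
    gW <- crossprod(a_prev, delta)
    if (l2 > 0 && net$act[i] == "lrelu")  # hidden layers carry the L2 penalty
      gW <- gW + 2 * l2 * net$layers[[i]]$W
    grads[[i]] <- list(W = gW, b = colSums(delta))
    delta <- tcrossprod(delta, net$layers[[i]]$W)
  }
  list(grads = grads, dinput = delta)
}

adam_new <- function(net) {
  lapply(net$layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    s <- state[[i]]; g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

## ---------------------------------------------------------------------------

#' Build an untrained GAN
#'
#' Constructs the generator (`latent_dim -> gen_hidden -> n_snps`, LeakyReLU
#' hidden activations, tanh output) and discriminator (`n_snps -> disc_hidden
#' -> 1`, LeakyReLU hidden, sigmoid output) with seeded Glorot-uniform
#' initialisation.
#'
#' @param config a [gan_config()].
#' @param seed integer seed for the initial weights.
#' @return list of class `gan_model` with elements `generator`,
#'   `discriminator`, `config`.
#' @export
build_gan <- function(config, seed = 1L) {
  stopifnot(inherits(config, "gan_config"))
  withr_seed(seed, {
    gen <- mlp_new(c(config$latent_dim, config$gen_hidden, config$n_snps),
                   c("lrelu", "lrelu", "tanh"))
    # final layer linear = logits; sigmoid is folded into the loss
    disc <- mlp_new(c(config$n_snps, config$disc_hidden, 1L),
                    c("lrelu", "lrelu", "linear"))
    structure(list(generator = gen, discriminator = disc, config = config),
              class = "gan_model")
  })
}

#' @export
print.gan_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<gan_model: generator %d-%d-%d-%d (tanh out), ",
                     "discriminator %d-%d-%d-1 (sigmoid out)>\n"),
              cfg$latent_dim, cfg$gen_hidden[1], cfg$gen_hidden[2], cfg$n_snps,
              cfg$n_snps, cfg$disc_hidden[1], cfg$disc_hidden[2]))
  invisible(x)
}

# generator forward pass on latent rows
gan_generate_raw <- function(model, z) {
  mlp_forward(model$generator, z, model$config$leaky_alpha)$out
}

# discriminator probability that rows of x are real
gan_discriminate <- function(model, x) {
  sigmoid(mlp_forward(model$discriminator, x, model$config$leaky_alpha)$out[, 1L])
}

# mean binary cross-entropy on logits; dloss/dlogit = (sigmoid(z) - y) / n
bce_logit_grad <- function(logits, y) {
  p <- sigmoid(logits)
  list(loss = -mean(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12))),
       dlogit = (p - y) / length(y))
}

#' Train the GAN adversarially
#'
#' Splits the data 3:1 into a training and a held-out validation part, then
#' alternates per minibatch: a discriminator update on a real batch (labels
#' smoothed uniformly into \[1 - smoothing_upper, 1\]) plus a generated batch
#' (labels 0), followed by a generator update through the frozen
#' discriminator (generated batch, labels 1).  Both networks use Adam with
#' binary cross-entropy.  Every `probe_interval` epochs the nearest-neighbour
#' adversarial accuracy between a fresh artificial sample and the held-out
#' validation split is recorded; with `stop_at_aats = TRUE` training stops
#' once the probe sits within `aats_tol` of 0.5 twice in a row (the default
#' trains to `epochs`, since the probe alone rarely defines a clean stopping
#' point).
#'
#' @param M training [haplotype_matrix()].
#' @param config a [gan_config()]; defaults to `gan_config(n_snps(M))` with
#'   any `...` overrides applied.
#' @param ... passed to [gan_config()] when `config` is not supplied.
#' @param validation optional [haplotype_matrix()] used as the probe's
#'   held-out set; when supplied the model trains on all of `M` instead of
#'   carving out the internal 3:1 split.
#' @param keep_best if `TRUE`, snapshot the networks at every probe and
#'   return the snapshot whose probe AA_TS is closest to the ideal 0.5
#'   (adversarial training does not converge monotonically, so held-out
#'   model selection over the probe trace is markedly more stable than
#'   taking the final epoch).
#' @param stop_at_aats,aats_tol optional early stopping on the probe.
#' @param seed integer seed governing the split, initialisation and all
#'   training randomness.
#' @return list of class `gan_fit`: `model` (`gan_model`), `history` (tibble
#'   with epoch, mean discriminator/generator loss, probe AA_TS where
#'   evaluated) and `validation` (the untouched held-out split).
#' @export
train_gan <- function(M, config = NULL, ..., validation = NULL,
                      keep_best = FALSE, stop_at_aats = FALSE,
                      aats_tol = 0.05, seed = 1L) {
  M <- validate_haplotype_matrix(M)
  if (is.null(config)) config <- gan_config(n_snps = ncol(M), ...)
  stopifnot(inherits(config, "gan_config"))
  if (config$n_snps != ncol(M))
    stop("config n_snps does not match the data", call. = FALSE)
  split <- if (is.null(validation)) {
    split_train_test(M, ratio = config$train_fraction, seed = seed)
  } else list(train = M, test = validate_haplotype_matrix(validation))
  x_train <- hap_values(split$train)
  if (config$rescale) x_train <- 2 * x_train - 1
  n <- nrow(x_train)
  if (config$batch_size > n)
    stop("batch size exceeds the training split", call. = FALSE)
  model <- build_gan(config, seed = seed)
  a <- config$leaky_alpha
  hist_epoch <- integer(0); hist_d <- numeric(0); hist_g <- numeric(0)
  hist_aats <- numeric(0)
  best <- list(score = Inf, generator = NULL, discriminator = NULL,
               epoch = NA_integer_)
  withr_seed(seed + 1L, {
    st_d <- adam_new(model$discriminator)
    st_g <- adam_new(model$generator)
    t_d <- 0L; t_g <- 0L
    prev_ok <- FALSE
    d_losses <- g_losses <- rep(NA_real_, config$probe_interval)
    for (ep in seq_len(config$epochs)) {
      # one epoch = one adversarial round on a randomly drawn minibatch
      {
        bi <- (ep - 1L) %% config$probe_interval + 1L
        rows <- sample.int(n, config$batch_size, replace = TRUE)
        real <- x_train[rows, , drop = FALSE]
        nb <- nrow(real)
        z <- matrix(stats::rnorm(nb * config$latent_dim), nb)
        fake <- gan_generate_raw(model, z)
        # --- discriminator: one step on the real batch (smoothed labels),
        #     then one step on the generated batch (labels 0)
        d_loss_b <- 0
        for (half in list(list(x = real,
                               y = stats::runif(nb, 1 - config$smoothing_upper,
                                                1)),
                          list(x = fake, y = rep(0, nb)))) {
          cache_d <- mlp_forward(model$discriminator, half$x, a)
          bd <- bce_logit_grad(cache_d$out[, 1L], half$y)
          gr <- mlp_backward(model$discriminator, cache_d,
                             matrix(bd$dlogit, ncol = 1L), a, l2 = config$l2)
          up <- adam_step(model$discriminator, st_d, gr$grads, config$lr_disc,
                          t_d <- t_d + 1L)
          model$discriminator <- up$net; st_d <- up$state
          d_loss_b <- d_loss_b + bd$loss / 2
        }
        d_losses[bi] <- d_loss_b
        # --- generator step through the frozen discriminator (labels 1)
        z <- matrix(stats::rnorm(nb * config$latent_dim), nb)
        cache_g <- mlp_forward(model$generator, z, a)
        cache_d2 <- mlp_forward(model$discriminator, cache_g$out, a)
        bg <- bce_logit_grad(cache_d2$out[, 1L], rep(1, nb))
        back_d <- mlp_backward(model$discriminator, cache_d2,
                               matrix(bg$dlogit, ncol = 1L), a, l2 = 0)
        gr_g <- mlp_backward(model$generator, cache_g, back_d$dinput, a,
                             l2 = config$l2)
        up <- adam_step(model$generator, st_g, gr_g$grads, config$lr_gan,
                        t_g <- t_g + 1L)
        model$generator <- up$net; st_g <- up$state
        g_losses[bi] <- bg$loss
      }
      if (!is.finite(d_losses[bi]) || !is.finite(g_losses[bi]))
        stop("non-finite loss at epoch ", ep, "; training diverged",
             call. = FALSE)
      aats_now <- NA_real_
      if (ep %% config$probe_interval == 0L || ep == config$epochs) {
        ag <- gan_threshold(model,
                            gan_generate_raw(model,
                              matrix(stats::rnorm(n_haplotypes(split$test) *
                                                    config$latent_dim),
                                     n_haplotypes(split$test))))
        aats_now <- adversarial_accuracy(
          nearest_neighbor_profile(split$test, haplotype_matrix(ag)))$aa_ts
        hist_epoch <- c(hist_epoch, ep)
        hist_d <- c(hist_d, mean(d_losses, na.rm = TRUE))
        hist_g <- c(hist_g, mean(g_losses, na.rm = TRUE))
        hist_aats <- c(hist_aats, aats_now)
        if (keep_best && !is.na(aats_now) &&
            abs(aats_now - 0.5) < best$score) {
          best <- list(score = abs(aats_now - 0.5),
                       generator = model$generator,
                       discriminator = model$discriminator, epoch = ep)
        }
        if (stop_at_aats && !is.na(aats_now)) {
          ok <- abs(aats_now - 0.5) < aats_tol
          if (ok && prev_ok) break
          prev_ok <- ok
        }
      }
    }
  })
  if (keep_best && !is.null(best$generator)) {
    model$generator <- best$generator
    model$discriminator <- best$discriminator
  }
  structure(list(model = model,
                 history = tibble::tibble(epoch = hist_epoch, d_loss = hist_d,
                                          g_loss = hist_g,
                                          aats_probe = hist_aats),
                 best_epoch = if (keep_best) best$epoch else NA_integer_,
                 validation = split$test),
            class = "gan_fit")
}

#' @export
print.gan_fit <- function(x, ...) {
  print(x$model)
  if (nrow(x$history))
    cat(sprintf("  trained %d epochs; final d_loss %.3f, g_loss %.3f\n",
                max(x$history$epoch), utils::tail(x$history$d_loss, 1),
                utils::tail(x$history$g_loss, 1)))
  invisible(x)
}

# threshold raw tanh outputs to 0/1 according to the config's data mode
gan_threshold <- function(model, raw) {
  cut <- if (model$config$rescale) 0 else 0.5
  matrix(as.integer(raw >= cut), nrow(raw), ncol(raw))
}

#' Generate artificial haplotypes from a trained GAN
#'
#' Draws `n` latent vectors from the standard Gaussian, maps them through the
#' generator and rounds every element to 0 or 1 (threshold 0.5 in the
#' default 0/1 data mode, 0 in the rescaled \[-1, 1\] mode).
#'
#' @param model a `gan_model` or `gan_fit`.
#' @param n number of haplotypes to generate (> 0).
#' @param seed integer seed.
#' @return a [haplotype_matrix()] of `n` artificial haplotypes.
#' @export
generate_gan <- function(model, n, seed = 1L) {
  if (inherits(model, "gan_fit")) model <- model$model
  stopifnot(inherits(model, "gan_model"))
  if (n < 1L) stop("n must be positive", call. = FALSE)
  withr_seed(seed, {
    z <- matrix(stats::rnorm(n * model$config$latent_dim), n)
    haplotype_matrix(gan_threshold(model, gan_generate_raw(model, z)))
  })
}
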