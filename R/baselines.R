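#' Per-site Bernoulli baseline
#'
#' The simplest generative baseline: each site is an independent Bernoulli
#' draw parameterised by the alternative-allele frequency observed in the
#' training data.  It preserves marginal frequencies exactly in expectation
#' and destroys all linkage and population structure.
#'
#' @param train a [haplotype_matrix()] of training haplotypes.
#' @return numeric vector of per-site frequencies (class `ag_bernoulli`).
#' @export
fit_bernoulli <- function(train) {
  train <- validate_haplotype_matrix(train)
  structure(allele_frequencies(train), class = "ag_bernoulli",
            n_snps = ncol(train))
}

#' @rdname fit_bernoulli
#' @param freqs frequency vector (as returned by `fit_bernoulli`), entries in
#'   \[0, 1\].
#' @param n number of haplotypes to generate (> 0).
#' @param seed integer seed; generation is deterministic given the seed.
#' @return `generate_bernoulli`: a [haplotype_matrix()] of `n` haplotypes.
#' @export
generate_bernoulli <- function(freqs, n, seed = 1L) {
  freqs <- as.numeric(freqs)
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]",
                                       call. = FALSE)
  if (n < 1L) stop("n must be positive", call. = FALSE)
  L <- length(freqs)
  withr_seed(seed, {
    haplotype_matrix(matrix(stats::rbinom(n * L, 1L, rep(freqs, each = n)),
                            n, L))
  })
}

#' Incremental-window Markov-chain baseline
#'
#' Fits the empirical left-to-right haplotype model: position 1 is a
#' Bernoulli draw at the training frequency; position p is drawn from the
#' observed conditional frequency given the previous `min(p - 1, window)`
#' alleles, with the context length growing incrementally up to `window`
#' (typical window sizes: 5 or 10 SNPs).  Probabilities are raw observed
#' frequencies without pseudocounts.
#'
#' At generation time a context that never occurred in training is resolved
#' by backing off: the context is truncated one allele at a time (dropping
#' the oldest) until a seen context is found, with the marginal site
#' frequency as the final fallback.  This guarantees generation always
#' succeeds without smoothing hyperparameters.
#'
#' @param train a [haplotype_matrix()].
#' @param window maximum context length in SNPs (>= 1).
#' @return an object of class `ag_markov` holding, for every position and
#'   every context length up to the window, the conditional P(allele = 1)
#'   tables.
#' @export
fit_markov <- function(train, window = 10L) {
  train <- validate_haplotype_matrix(train)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  v <- unclass(train)
  L <- ncol(v)
  # tables[[p]][[l + 1]]: named vector of P(h_p = 1 | last l alleles), names
  # are the context strings; l = 0 entry is the marginal frequency scalar.
  tables <- vector("list", L)
  for (p in seq_len(L)) {
    wp <- min(p - 1L, window)
    tp <- vector("list", wp + 1L)
    tp[[1L]] <- stats::setNames(mean(v[, p]), "")
    if (wp >= 1L) for (l in seq_len(wp)) {
      ctx <- do.call(paste0, as.data.frame(v[, (p - l):(p - 1L), drop = FALSE]))
      tp[[l + 1L]] <- vapply(split(v[, p], ctx), mean, numeric(1))
    }
    tables[[p]] <- tp
  }
  structure(list(window = as.integer(window), n_snps = L, tables = tables),
            class = "ag_markov")
}

#' @rdname fit_markov
#' @param model a fitted `ag_markov` model.
#' @param n number of haplotypes to generate (> 0).
#' @param seed integer seed.
#' @return `generate_markov`: a [haplotype_matrix()] of `n` haplotypes.
#' @export
generate_markov <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "ag_markov"))
  if (n < 1L) stop("n must be positive", call. = FALSE)
  L <- model$n_snps
  withr_seed(seed, {
    gen <- matrix(0L, n, L)
    for (p in seq_len(L)) {
      tp <- model$tables[[p]]
      wp <- length(tp) - 1L
      p1 <- rep(NA_real_, n)
      l <- wp
      while (l >= 1L && anyNA(p1)) {
        need <- which(is.na(p1))
        ctx <- do.call(paste0,
                       as.data.frame(gen[need, (p - l):(p - 1L), drop = FALSE]))
        hit <- match(ctx, names(tp[[l + 1L]]))
        ok <- !is.na(hit)
        p1[need[ok]] <- tp[[l + 1L]][hit[ok]]
        l <- l - 1L
      }
      p1[is.na(p1)] <- tp[[1L]]  # marginal-frequency fallback
      gen[, p] <- stats::rbinom(n, 1L, p1)
    }
    haplotype_matrix(gen)
  })
}

#' @export
print.ag_markov <- function(x, ...) {
  n_ctx <- sum(vapply(x$tables, function(tp) sum(lengths(tp)), numeric(1)))
  cat(sprintf("<ag_markov: window %d, %d SNPs, %d stored contexts>\n",
              x$window, x$n_snps, n_ctx))
  invisible(x)
}
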