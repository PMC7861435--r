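#' Simulate structured haplotypes (Balding-Nichols model)
#'
#' Generates a multi-population haplotype matrix with a tunable level of
#' population differentiation.  For each SNP an ancestral alternative-allele
#' frequency p is drawn from the ancestral law; each population then receives
#' its own frequency from a Beta distribution with mean p and variance
#' `differentiation * p * (1 - p)` (the Balding-Nichols parameterisation, so
#' `differentiation` plays the role of F_ST); alleles are drawn independently
#' per haplotype and site.  Sites are independent, so any linkage
#' disequilibrium must be layered on with [simulate_mosaic()].
#'
#' The defaults (2 populations of 250 haplotypes, 100 SNPs, differentiation
#' 0.2) are the desk-scale study conditions used throughout the package's
#' end-to-end evaluations.
#'
#' @param n_pops number of populations.
#' @param haplotypes_per_pop haplotypes per population.
#' @param n_snps number of SNPs.
#' @param differentiation F_ST-like scalar, strictly inside (0, 1).
#' @param ancestral_min,ancestral_max range of the uniform ancestral
#'   frequency law (defaults 0.05-0.95).
#' @param rare_fraction fraction of sites whose ancestral frequency is drawn
#'   from a rare-allele spike Beta(0.2, 2) instead of the uniform law
#'   (default 0 = off); useful for exercising low-frequency behaviour.
#' @param seed integer seed; the same seed reproduces the matrix bitwise.
#' @return a [haplotype_matrix()] with `labels` `"POP1"..."POPk"`.
#' @examples
#' M <- simulate_structured(seed = 7)
#' table(hap_labels(M))
#' @export
simulate_structured <- function(n_pops = 2L, haplotypes_per_pop = 250L,
                                n_snps = 100L, differentiation = 0.2,
                                ancestral_min = 0.05, ancestral_max = 0.95,
                                rare_fraction = 0, seed = 1L) {
  stopifnot(n_pops >= 1L, haplotypes_per_pop >= 1L, n_snps >= 1L,
            rare_fraction >= 0, rare_fraction <= 1,
            ancestral_min > 0, ancestral_max < 1,
            ancestral_min < ancestral_max)
  if (!(differentiation > 0 && differentiation < 1))
    stop("differentiation must be strictly inside (0, 1)", call. = FALSE)
  f <- differentiation
  withr_seed(seed, {
    p <- stats::runif(n_snps, ancestral_min, ancestral_max)
    if (rare_fraction > 0) {
      is_rare <- stats::runif(n_snps) < rare_fraction
      # spike concentrated near 0; clamp away from exact fixation
      p[is_rare] <- pmin(pmax(stats::rbeta(sum(is_rare), 0.2, 2), 1e-3),
                         1 - 1e-3)
    }
    # Beta with mean p and variance f*p*(1-p): shape1 = p(1-f)/f, shape2 = (1-p)(1-f)/f
    a <- p * (1 - f) / f
    b <- (1 - p) * (1 - f) / f
    if (any(!is.finite(a)) || any(a <= 0) || any(b <= 0))
      stop("degenerate Beta parameters for the population frequencies",
           call. = FALSE)
    values <- matrix(0L, n_pops * haplotypes_per_pop, n_snps)
    for (k in seq_len(n_pops)) {
      pk <- stats::rbeta(n_snps, a, b)
      rows <- (k - 1L) * haplotypes_per_pop + seq_len(haplotypes_per_pop)
      values[rows, ] <- matrix(
        stats::rbinom(haplotypes_per_pop * n_snps, 1L,
                      rep(pk, each = haplotypes_per_pop)),
        haplotypes_per_pop, n_snps)
    }
    haplotype_matrix(values,
                     labels = rep(paste0("POP", seq_len(n_pops)),
                                  each = haplotypes_per_pop))
  })
}

#' Simulate mosaic haplotypes by template copying
#'
#' A Li-Stephens-style copying process that manufactures linkage
#' disequilibrium: each output haplotype walks left to right across the SNPs
#' copying one founder haplotype, switches to a uniformly chosen founder with
#' probability `switch_rate` at each step, and finally flips each copied
#' allele with probability `mutation_rate`.  With `switch_rate = 0` and
#' `mutation_rate = 0` every output row is an exact founder row; with
#' `switch_rate = 1` sites become independent draws from the founder pool and
#' LD collapses to the unlinked baseline.
#'
#' @param founders a [haplotype_matrix()] of template haplotypes.
#' @param n_out number of haplotypes to generate.
#' @param switch_rate per-SNP template-switch probability in \[0, 1\].
#' @param mutation_rate per-site allele-flip probability in \[0, 1\].
#' @param seed integer seed.
#' @return a [haplotype_matrix()] with `n_out` rows, inheriting the founders'
#'   positions and SNP ids.
#' @export
simulate_mosaic <- function(founders, n_out, switch_rate = 0.05,
                            mutation_rate = 0.001, seed = 1L) {
  founders <- validate_haplotype_matrix(founders)
  stopifnot(n_out >= 1L,
            switch_rate >= 0, switch_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  fv <- unclass(founders)
  n_f <- nrow(fv)
  L <- ncol(fv)
  withr_seed(seed, {
    # current template index per output haplotype, resampled where a switch fires
    tmpl <- sample.int(n_f, n_out, replace = TRUE)
    values <- matrix(0L, n_out, L)
    for (t in seq_len(L)) {
      if (t > 1L) {
        sw <- stats::runif(n_out) < switch_rate
        if (any(sw)) tmpl[sw] <- sample.int(n_f, sum(sw), replace = TRUE)
      }
      values[, t] <- fv[tmpl, t]
    }
    if (mutation_rate > 0) {
      flips <- matrix(stats::runif(n_out * L) < mutation_rate, n_out, L)
      values[flips] <- 1L - values[flips]
    }
    hap_like(values, founders)
  })
}
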