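## Fidelity and privacy metrics for (real, artificial) haplotype dataset pairs.
## All distance-based statistics use the Hamming distance on alleles, the
## natural metric for binary haplotypes and the one matching "pairwise
## difference" counts; it is exposed where a choice exists.

# Hamming distances between all rows of A and all rows of B (n_A x n_B)
hamming_cross <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  d <- outer(rowSums(A), rowSums(B), `+`) - 2 * tcrossprod(A, B)
  round(pmax(d, 0))
}

# Hamming distances among rows of A (symmetric, zero diagonal)
hamming_within <- function(A) hamming_cross(A, A)

#' Per-site allele-frequency comparison
#'
#' Pairs the alternative-allele frequency of every SNP in the real and
#' artificial datasets and reports their Pearson correlation — the headline
#' frequency-fidelity statistic.
#'
#' @param real,art [haplotype_matrix()] objects with equal SNP counts.
#' @return list with `table` (tibble: site, freq_real, freq_art) and
#'   `correlation` (scalar; `NA` with a warning when either frequency vector
#'   has zero variance).
#' @export
allele_freq_comparison <- function(real, art) {
  fr <- allele_frequencies(real)
  fa <- allele_frequencies(art)
  if (length(fr) != length(fa))
    stop("real and artificial datasets must cover the same SNPs", call. = FALSE)
  corr <- if (stats::sd(fr) == 0 || stats::sd(fa) == 0) {
    warning("zero-variance frequency vector; correlation undefined")
    NA_real_
  } else stats::cor(fr, fa)
  list(table = tibble::tibble(site = seq_along(fr), freq_real = fr,
                              freq_art = fa),
       correlation = corr)
}

#' Linkage disequilibrium matrix and binned decay curves
#'
#' `ld_matrix()` returns the squared Pearson correlation r^2 between every
#' pair of SNP columns (`NA` rows/columns for fixed sites).  `ld_decay()`
#' first removes sites fixed in at least one of the two datasets, computes
#' both r^2 matrices, stratifies pairwise SNP distances (index distance, or
#' bp when positions are available) into `n_bins` equal-width bins, and
#' averages r^2 over the pairs in each bin.
#'
#' @param M,real,art [haplotype_matrix()] objects.
#' @param n_bins number of distance bins (default 50).
#' @return `ld_matrix`: numeric matrix `n_snps x n_snps`.  `ld_decay`:
#'   tibble with `bin`, `dist_mid`, `mean_r2_real`, `mean_r2_art`, `n_pairs`.
#' @export
ld_matrix <- function(M) {
  v <- hap_values(M)
  suppressWarnings(stats::cor(v))^2
}

#' @rdname ld_matrix
#' @export
ld_decay <- function(real, art, n_bins = 50L) {
  fr <- allele_frequencies(real)
  fa <- allele_frequencies(art)
  if (length(fr) != length(fa))
    stop("datasets must cover the same SNPs", call. = FALSE)
  keep <- fr > 0 & fr < 1 & fa > 0 & fa < 1   # fixed in either -> removed
  if (sum(keep) < 2L)
    stop("fewer than 2 sites segregate in both datasets", call. = FALSE)
  pos <- hap_positions(real)
  coord <- if (!is.null(pos)) pos[keep] else which(keep)
  r2r <- ld_matrix(haplotype_matrix(unclass(real)[, keep, drop = FALSE]))
  r2a <- ld_matrix(haplotype_matrix(unclass(art)[, keep, drop = FALSE]))
  iu <- which(upper.tri(r2r), arr.ind = TRUE)
  d <- abs(coord[iu[, 2L]] - coord[iu[, 1L]])
  edges <- seq(min(d), max(d), length.out = n_bins + 1L)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  bin_f <- factor(bin, levels = seq_len(n_bins))
  agg <- function(x) as.numeric(tapply(x, bin_f, mean, na.rm = TRUE))
  counts <- as.integer(table(bin_f))
  tibble::tibble(bin = seq_len(n_bins),
                 dist_mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 mean_r2_real = agg(r2r[iu]),
                 mean_r2_art = agg(r2a[iu]),
                 n_pairs = counts)
}

# connected 3rd-order moment of three 0/1 columns at allele combination (a,b,c)
three_point_c <- function(x, y, z, a = 1, b = 1, c = 1) {
  xa <- as.numeric(x == a); yb <- as.numeric(y == b); zc <- as.numeric(z == c)
  mean(xa * yb * zc) -
    mean(xa * yb) * mean(zc) -
    mean(xa * zc) * mean(yb) -
    mean(yb * zc) * mean(xa) +
    2 * mean(xa) * mean(yb) * mean(zc)
}

#' Three-point correlations of SNP triplets
#'
#' Measures correlation beyond pairwise LD: for SNPs i, j, k and alleles
#' (a, b, c) the connected third moment
#' `c_ijk = f_ijk - f_ij f_k - f_ik f_j - f_jk f_i + 2 f_i f_j f_k`.
#' Triplets are sampled as (i, i + s, i + 2s) for each requested separation s
#' (separations too large for the panel are skipped with a warning), plus
#' fully random triplets when `include_random = TRUE`.  The default evaluates
#' the (1, 1, 1) allele combination.
#'
#' @param M a [haplotype_matrix()].
#' @param separations SNP-index separations (reference protocol: 1, 4, 16,
#'   64, 256, 512, 1024).
#' @param n_triplets triplets sampled per separation (default 8000).
#' @param alleles length-3 vector in \{0,1\}^3 (default `c(1, 1, 1)`).
#' @param include_random also sample fully random triplets.
#' @param return_values attach the raw per-triplet values as a list-column.
#' @param seed integer seed for triplet sampling.
#' @return tibble with one row per separation: `separation` (character),
#'   `n_triplets`, `mean_c`, `sd_c`, `q05`, `q95` (and `values` if requested).
#' @export
three_point_corr <- function(M, separations = c(1, 4, 16, 64, 256, 512, 1024),
                             n_triplets = 8000L, alleles = c(1, 1, 1),
                             include_random = TRUE, return_values = FALSE,
                             seed = 1L) {
  stopifnot(all(alleles %in% c(0, 1)), length(alleles) == 3L)
  v <- hap_values(M)
  L <- ncol(v)
  labels <- as.character(separations)
  if (include_random) labels <- c(labels, "random")
  withr_seed(seed, {
    rows <- lapply(labels, function(lab) {
      if (lab == "random") {
        if (L < 3L) { warning("fewer than 3 SNPs; random triplets skipped")
          return(NULL) }
        trip <- t(replicate(n_triplets, sample.int(L, 3L)))
      } else {
        s <- as.integer(lab)
        if (2L * s >= L) {
          warning("separation ", s, " too large for ", L, " SNPs; skipped")
          return(NULL)
        }
        i <- sample.int(L - 2L * s, n_triplets, replace = TRUE)
        trip <- cbind(i, i + s, i + 2L * s)
      }
      cval <- vapply(seq_len(nrow(trip)), function(r)
        three_point_c(v[, trip[r, 1L]], v[, trip[r, 2L]], v[, trip[r, 3L]],
                      alleles[1L], alleles[2L], alleles[3L]),
        numeric(1))
      out <- tibble::tibble(separation = lab, n_triplets = nrow(trip),
                            mean_c = mean(cval), sd_c = stats::sd(cval),
                            q05 = stats::quantile(cval, 0.05, names = FALSE),
                            q95 = stats::quantile(cval, 0.95, names = FALSE))
      if (return_values) out$values <- list(cval)
      out
    })
    dplyr::bind_rows(rows)
  })
}

#' Empirical 1-D Wasserstein distance
#'
#' Earth-mover distance between the empirical distributions of two numeric
#' samples (the integral of the absolute CDF difference); used to compare
#' pairwise-difference distributions.
#'
#' @param a,b numeric vectors (any lengths).
#' @return non-negative scalar.
#' @export
wasserstein_1d <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  xs <- sort(c(a, b))
  if (length(xs) < 2L) return(0)
  d <- diff(xs)
  grid <- xs[-length(xs)]
  Fa <- findInterval(grid, sort(a)) / length(a)
  Fb <- findInterval(grid, sort(b)) / length(b)
  sum(abs(Fa - Fb) * d)
}

#' Pairwise-distance distributions within and between datasets
#'
#' Hamming distances over all unordered pairs within the real set, within
#' the artificial set, and over all real-artificial pairs; the 1-D
#' Wasserstein distance between the two within-set distributions; and the
#' number of exactly-zero between-distances (real genomes copied verbatim
#' into the artificial set — ideally 0).
#'
#' @param real,art [haplotype_matrix()] objects over the same SNPs.
#' @return list of class `pairwise_dist`: `within_real`, `within_art`,
#'   `between` (numeric vectors), `wasserstein_within`, `n_zero_between`.
#' @export
pairwise_distance_distributions <- function(real, art) {
  vr <- hap_values(real); va <- hap_values(art)
  dr <- hamming_within(vr)[upper.tri(diag(nrow(vr)))]
  da <- hamming_within(va)[upper.tri(diag(nrow(va)))]
  db <- as.vector(hamming_cross(vr, va))
  structure(list(within_real = dr, within_art = da, between = db,
                 wasserstein_within = wasserstein_1d(dr, da),
                 n_zero_between = sum(db == 0)),
            class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat(sprintf(paste0("<pairwise_dist: within-real median %g, within-art ",
                     "median %g,\n  Wasserstein(within) = %.4g, ",
                     "%d identical real/art pair(s)>\n"),
              stats::median(x$within_real), stats::median(x$within_art),
              x$wasserstein_within, x$n_zero_between))
  invisible(x)
}

#' Nearest-neighbour distance profile
#'
#' The four distance vectors underlying the adversarial-accuracy statistics:
#' for every real haplotype its nearest artificial neighbour (`d_ts`) and
#' nearest other real haplotype (`d_tt`, leave-self-out), and symmetrically
#' for artificial haplotypes (`d_st`, `d_ss`).
#'
#' @param real,art [haplotype_matrix()] objects over the same SNPs.
#' @return list of class `neighbor_distances` with `d_ts`, `d_st`, `d_tt`,
#'   `d_ss` and `metric = "hamming"`.
#' @export
nearest_neighbor_profile <- function(real, art) {
  vr <- hap_values(real); va <- hap_values(art)
  if (nrow(vr) < 2L || nrow(va) < 2L)
    stop("need at least 2 haplotypes per dataset (self-excluded distances)",
         call. = FALSE)
  cross <- hamming_cross(vr, va)
  wr <- hamming_within(vr); diag(wr) <- Inf
  wa <- hamming_within(va); diag(wa) <- Inf
  structure(list(d_ts = apply(cross, 1L, min),
                 d_st = apply(cross, 2L, min),
                 d_tt = apply(wr, 1L, min),
                 d_ss = apply(wa, 1L, min),
                 metric = "hamming"),
            class = "neighbor_distances")
}

#' @export
print.neighbor_distances <- function(x, ...) {
  cat(sprintf(paste0("<neighbor_distances (%s): %d real, %d artificial;\n",
                     "  median d_TS %g, d_TT %g, d_ST %g, d_SS %g>\n"),
              x$metric, length(x$d_ts), length(x$d_st),
              stats::median(x$d_ts), stats::median(x$d_tt),
              stats::median(x$d_st), stats::median(x$d_ss)))
  invisible(x)
}

#' Nearest-neighbour adversarial accuracy
#'
#' `AA_truth` is the fraction of real haplotypes strictly closer to another
#' real haplotype than to any artificial one
#' (`mean(d_TS > d_TT)`; ties count as 0); `AA_syn` is the symmetric
#' artificial-side statistic; `AA_TS` is their average.  0.5 means the two
#' sets are mutually indistinguishable; values below 0.5 indicate
#' overfitting (artificial points too close to real ones, a privacy risk),
#' above 0.5 underfitting.  `AA_truth` and `AA_syn` are reported separately
#' because a balanced 0.5 can hide a 0/1 split between them.
#'
#' @param nd a [nearest_neighbor_profile()] result, or a real
#'   `haplotype_matrix` (with `art` supplied) from which one is computed.
#' @param art artificial dataset when `nd` is a haplotype matrix.
#' @return one-row tibble with `aa_truth`, `aa_syn`, `aa_ts`.
#' @export
adversarial_accuracy <- function(nd, art = NULL) {
  if (!inherits(nd, "neighbor_distances"))
    nd <- nearest_neighbor_profile(nd, art)
  if (length(nd$d_ts) != length(nd$d_st))
    warning("unequal real/artificial sizes (", length(nd$d_ts), " vs ",
            length(nd$d_st), "); AA statistics assume equal n")
  aa_truth <- mean(nd$d_ts > nd$d_tt)
  aa_syn <- mean(nd$d_st > nd$d_ss)
  tibble::tibble(aa_truth = aa_truth, aa_syn = aa_syn,
                 aa_ts = (aa_truth + aa_syn) / 2)
}

#' @rdname adversarial_accuracy
#' @param real real dataset.
#' @return `aa_ts_score`: the scalar AA_TS.
#' @export
aa_ts_score <- function(real, art) {
  adversarial_accuracy(nearest_neighbor_profile(real, art))$aa_ts
}

#' Privacy loss of an artificial dataset
#'
#' `AA_TS(test, art) - AA_TS(train, art)`: positive values mean the
#' artificial set sits closer to the training haplotypes than to an
#' independent test set drawn from the same population — leakage of training
#' information.  The score approximately ranges from -0.5 to 0.5; values
#' outside that band are flagged with a warning.
#'
#' @param train,test disjoint real datasets (training and held-out).
#' @param art artificial dataset.
#' @return scalar privacy loss.
#' @export
privacy_loss <- function(train, test, art) {
  pl <- aa_ts_score(test, art) - aa_ts_score(train, art)
  if (abs(pl) > 0.5 + 1e-12)
    warning("privacy loss ", signif(pl, 3),
            " outside the typical [-0.5, 0.5] range")
  pl
}

#' Sensitivity of the privacy scores to spiked-in training haplotypes
#'
#' For each k in `spike_counts`, replaces k random artificial rows with k
#' random training rows and recomputes AA_TS against the training set, the
#' test set, and the privacy loss — probing how sharply the scores react to
#' verbatim leakage.
#'
#' @param train,test,art as in [privacy_loss()].
#' @param spike_counts numbers of rows to replace (0 = unspiked baseline).
#' @param seed integer seed for the row choices.
#' @return tibble with `n_spiked`, `aa_ts_train`, `aa_ts_test`,
#'   `privacy_loss`.
#' @export
spike_in_sensitivity <- function(train, test, art,
                                 spike_counts = c(0L, 1L, 10L, 50L, 100L),
                                 seed = 1L) {
  va <- unclass(art); vt <- unclass(train)
  spike_counts <- as.integer(spike_counts)
  stopifnot(all(spike_counts >= 0L), all(spike_counts <= nrow(va)),
            all(spike_counts <= nrow(vt)))
  withr_seed(seed, {
    rows <- lapply(spike_counts, function(k) {
      m <- va
      if (k > 0L)
        m[sample.int(nrow(va), k), ] <- vt[sample.int(nrow(vt), k), ,
                                           drop = FALSE]
      mixed <- haplotype_matrix(m)
      at <- aa_ts_score(train, mixed)
      ae <- aa_ts_score(test, mixed)
      tibble::tibble(n_spiked = k, aa_ts_train = at, aa_ts_test = ae,
                     privacy_loss = ae - at)
    })
    dplyr::bind_rows(rows)
  })
}

#' Joint principal component analysis of several datasets
#'
#' Fits a single PCA on the row-concatenation of all datasets and returns
#' each dataset's coordinates in that common space, so real and artificial
#' clouds are directly comparable.
#'
#' @param datasets named list of [haplotype_matrix()] objects over the same
#'   SNPs.
#' @param n_components principal components to retain (default 6).
#' @return object of class `joint_pca`: tibble with `dataset`, `row` and
#'   `PC1..PCk` columns; eigenvalues in `attr(, "eigenvalues")`.
#' @export
joint_pca <- function(datasets, n_components = 6L) {
  if (inherits(datasets, "haplotype_matrix")) datasets <- list(datasets)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  mats <- lapply(datasets, hap_values)
  L <- unique(vapply(mats, ncol, integer(1)))
  if (length(L) != 1L) stop("datasets must cover the same SNPs", call. = FALSE)
  combined <- do.call(rbind, mats)
  k <- min(n_components, ncol(combined), nrow(combined) - 1L)
  pc <- stats::prcomp(combined, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  out <- tibble::as_tibble(as.data.frame(scores))
  out <- dplyr::bind_cols(
    tibble::tibble(dataset = rep(names(datasets),
                                 vapply(mats, nrow, integer(1))),
                   row = unlist(lapply(mats, function(m) seq_len(nrow(m))))),
    out)
  structure(out, eigenvalues = pc$sdev[seq_len(k)]^2,
            class = c("joint_pca", class(out)))
}

# log-sum-exp over rows of a matrix (max.col avoids an interpreted apply)
row_lse <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

#' Entropic 2-D Wasserstein distance between point clouds
#'
#' Solves the entropic regularised optimal-transport problem with squared
#' Euclidean ground cost and uniform weights via log-domain Sinkhorn
#' iterations (with epsilon-annealing for small regularisation values) and
#' returns the transport cost of the converged plan.  The reference
#' regularisation for PC1/PC2 clouds is 0.001.
#'
#' @param cloud_a,cloud_b numeric matrices with the same number of columns
#'   (typically `n x 2`: the first two principal components).
#' @param reg entropic regularisation strength (> 0).
#' @param max_iter,tol Sinkhorn iteration cap per annealing stage and
#'   marginal-error tolerance; non-convergence is an error reporting the
#'   residual.
#' @return scalar transport cost (sum of plan * cost).
#' @export
wasserstein_2d <- function(cloud_a, cloud_b, reg = 0.001, max_iter = 10000L,
                           tol = 1e-5) {
  A <- as.matrix(cloud_a); B <- as.matrix(cloud_b)
  stopifnot(nrow(A) > 0, nrow(B) > 0, ncol(A) == ncol(B), reg > 0)
  n <- nrow(A); m <- nrow(B)
  C <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  C <- pmax(C, 0)
  la <- rep(log(1 / n), n); lb <- rep(log(1 / m), m)
  f <- numeric(n); g <- numeric(m)
  # epsilon-annealing: halve from a well-conditioned start down to reg
  eps_seq <- max(reg, max(C) / 10)
  while (utils::tail(eps_seq, 1) > reg) eps_seq <- c(eps_seq,
                                                     max(reg,
                                                         utils::tail(eps_seq,
                                                                     1) / 2))
  err <- Inf
  for (eps in eps_seq) {
    last_stage <- abs(eps - reg) < .Machine$double.eps
    nCe <- -C / eps
    for (it in seq_len(max_iter)) {
      f <- eps * (la - row_lse(sweep(nCe, 2L, g / eps, `+`)))
      g <- eps * (lb - row_lse(t(sweep(nCe, 1L, f / eps, `+`))))
      if (it %% 20L == 0L || it == max_iter) {
        logP <- sweep(sweep(nCe, 1L, f / eps, `+`), 2L, g / eps, `+`)
        err <- max(abs(rowSums(exp(logP)) - exp(la)))
        if (err < tol) break
      }
      if (!last_stage && it >= 50L) break  # warm start only; refine at target
    }
  }
  logP <- sweep(sweep(-C, 1L, f, `+`), 2L, g, `+`) / reg
  P <- exp(logP)
  err <- max(max(abs(rowSums(P) - exp(la))), max(abs(colSums(P) - exp(lb))))
  if (err > 1e-3)
    stop(sprintf("Sinkhorn iterations did not converge (marginal error %.2g)",
                 err), call. = FALSE)
  sum(P * C)
}

#' Fixed-site comparison between datasets
#'
#' Counts sites that are polymorphic in one dataset but fixed in the other —
#' the signature of generative models dropping rare alleles.  Counts are
#' split by the allele at which the site is fixed.
#'
#' @param real,art [haplotype_matrix()] objects over the same SNPs.
#' @return tibble with `fixed_in` ("art" or "real"), `allele` (0/1) and
#'   `count`; e.g. the "art"/0 row counts sites polymorphic in `real` but
#'   fixed at allele 0 in `art`.
#' @export
fixed_site_report <- function(real, art) {
  fr <- allele_frequencies(real)
  fa <- allele_frequencies(art)
  if (length(fr) != length(fa))
    stop("datasets must cover the same SNPs", call. = FALSE)
  poly_r <- fr > 0 & fr < 1
  poly_a <- fa > 0 & fa < 1
  tibble::tibble(
    fixed_in = c("art", "art", "real", "real"),
    allele = c(0L, 1L, 0L, 1L),
    count = c(sum(poly_r & fa == 0), sum(poly_r & fa == 1),
              sum(poly_a & fr == 0), sum(poly_a & fr == 1)))
}

#' Full evaluation of a (real, artificial) dataset pair
#'
#' Runs the complete fidelity/privacy suite with one seed: allele-frequency
#' comparison, LD correlation and decay curves, three-point correlations,
#' pairwise-distance distributions, nearest-neighbour profile and
#' adversarial accuracy, joint PCA with the entropic 2-D Wasserstein
#' distance on PC1/PC2, the fixed-site report, and — when disjoint `train`
#' and `test` sets are supplied — the privacy loss.
#'
#' @param real,art the dataset pair.
#' @param train,test optional disjoint real datasets enabling
#'   [privacy_loss()]; omitting either disables it (with a message).
#' @param n_bins LD decay bins.
#' @param separations,n_triplets three-point protocol (defaults scaled by
#'   panel size via [three_point_corr()]'s skipping rule).
#' @param ot_reg entropic regularisation for the 2-D Wasserstein distance.
#' @param seed seed for all stochastic metrics; re-running with the same
#'   seed reproduces the report bitwise.
#' @return object of class `evaluation_report`: a named list of the metric
#'   results plus a one-row `summary` tibble of the scalar statistics.
#' @export
evaluate_pair <- function(real, art, train = NULL, test = NULL, n_bins = 50L,
                          separations = c(1, 4, 16, 64, 256, 512, 1024),
                          n_triplets = 2000L, ot_reg = 0.001, seed = 1L) {
  real <- validate_haplotype_matrix(real)
  art <- validate_haplotype_matrix(art)
  freq <- allele_freq_comparison(real, art)
  ld <- tryCatch(ld_decay(real, art, n_bins = n_bins),
                 error = function(e) { message("LD decay skipped: ",
                                               conditionMessage(e)); NULL })
  r2r <- ld_matrix(real); r2a <- ld_matrix(art)
  iu <- upper.tri(r2r)
  ok <- is.finite(r2r[iu]) & is.finite(r2a[iu])
  ld_corr <- if (sum(ok) > 2) suppressWarnings(stats::cor(r2r[iu][ok],
                                                          r2a[iu][ok]))
             else NA_real_
  tp_real <- suppressWarnings(three_point_corr(real, separations, n_triplets,
                                               seed = seed))
  tp_art <- suppressWarnings(three_point_corr(art, separations, n_triplets,
                                              seed = seed))
  pw <- pairwise_distance_distributions(real, art)
  nd <- nearest_neighbor_profile(real, art)
  aa <- adversarial_accuracy(nd)
  pca <- joint_pca(list(real = real, art = art))
  w2 <- wasserstein_2d(as.matrix(pca[pca$dataset == "real", c("PC1", "PC2")]),
                       as.matrix(pca[pca$dataset == "art", c("PC1", "PC2")]),
                       reg = ot_reg)
  fixed <- fixed_site_report(real, art)
  pl <- NULL
  if (!is.null(train) && !is.null(test)) {
    pl <- privacy_loss(train, test, art)
  } else if (!is.null(train) || !is.null(test)) {
    message("privacy loss disabled: needs both a train and a test set")
  }
  summary <- tibble::tibble(
    freq_correlation = freq$correlation,
    ld_correlation = ld_corr,
    wasserstein_pairwise = pw$wasserstein_within,
    n_identical_pairs = pw$n_zero_between,
    aa_truth = aa$aa_truth, aa_syn = aa$aa_syn, aa_ts = aa$aa_ts,
    wasserstein_pca2d = w2,
    privacy_loss = if (is.null(pl)) NA_real_ else pl,
    n_fixed_in_art = sum(fixed$count[fixed$fixed_in == "art"]))
  structure(list(freq = freq, ld_decay = ld, ld_correlation = ld_corr,
                 three_point_real = tp_real, three_point_art = tp_art,
                 pairwise = pw, neighbors = nd, adversarial = aa,
                 pca = pca, wasserstein_pca2d = w2, fixed_sites = fixed,
                 privacy_loss = pl, summary = summary, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
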