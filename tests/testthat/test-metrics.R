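test_that("frequency, r2 and distance computations match brute-force oracles", {
  real <- random_hap(10, 8, seed = 1)
  art <- random_hap(9, 8, seed = 2)
  vr <- as.matrix(real); va <- as.matrix(art)
  # frequencies by direct count
  expect_equal(allele_frequencies(real),
               vapply(1:8, function(t) sum(vr[, t]) / 10, numeric(1)))
  # r2 matrix entry by entry
  r2 <- ld_matrix(real)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(r2[i, j], oracle_r2(vr[, i], vr[, j]), tolerance = 1e-12)
  # cross Hamming distances
  expect_equal(haplogen:::hamming_cross(vr, va), oracle_cross_dist(vr, va))
  # adversarial accuracy against the loop oracle
  aa <- adversarial_accuracy(suppressWarnings(
    nearest_neighbor_profile(real, art)))
  oa <- oracle_aa(vr, va)
  expect_equal(c(aa$aa_truth, aa$aa_syn, aa$aa_ts), unname(oa))
})

test_that("allele-frequency comparison handles identity and degeneracy", {
  real <- random_hap(30, 12, seed = 3)
  expect_equal(allele_freq_comparison(real, real)$correlation, 1)
  # column permutation with distinct frequencies lowers the correlation
  perm <- haplotype_matrix(as.matrix(real)[, c(2:12, 1)])
  expect_lt(allele_freq_comparison(real, perm)$correlation, 1)
  flat <- haplotype_matrix(matrix(rep(c(0, 1), each = 12), 2, 12,
                                  byrow = TRUE))
  expect_warning(out <- allele_freq_comparison(flat, real), "zero-variance")
  expect_true(is.na(out$correlation))
})

test_that("LD decay removes fixed-in-either sites and r2 identities hold", {
  set.seed(4)
  v <- cbind(rbinom(40, 1, 0.5), 0, rbinom(40, 1, 0.5))
  v[, 3] <- v[, 1]                     # duplicated column: r2 = 1
  real <- haplotype_matrix(v)
  expect_equal(ld_matrix(real)[1, 3], 1)
  art <- random_hap(40, 3, seed = 5)
  curve <- ld_decay(real, art, n_bins = 2)
  # column 2 is fixed in real: only the pair (1,3) survives, distance 2
  expect_equal(sum(curve$n_pairs), 1L)
  expect_equal(curve$mean_r2_real[!is.na(curve$mean_r2_real)], 1)
  all_fixed <- haplotype_matrix(matrix(1, 5, 3))
  expect_error(ld_decay(all_fixed, art), "fewer than 2 sites")
})

test_that("null LD between independent sites sits at the 1/(n-1) scale", {
  M <- random_hap(10000, 30, seed = 6, p = rep(0.5, 30))
  r2 <- ld_matrix(M)
  m <- mean(r2[upper.tri(r2)])
  expect_lt(abs(m - 1 / (10000 - 1)), 5e-5)
})

test_that("three-point correlation matches its printed-formula oracle", {
  # worked 4-haplotype, 3-SNP toy evaluated by direct counting
  M <- haplotype_matrix(rbind(c(1, 1, 1), c(1, 0, 1), c(0, 1, 0),
                              c(1, 1, 0)))
  v <- as.matrix(M)
  for (al in list(c(1, 1, 1), c(0, 1, 1), c(1, 0, 1), c(0, 0, 0)))
    expect_equal(haplogen:::three_point_c(v[, 1], v[, 2], v[, 3],
                                          al[1], al[2], al[3]),
                 oracle_c3(v[, 1], v[, 2], v[, 3], al[1], al[2], al[3]),
                 tolerance = 1e-12)
  # fixed third site: algebraic cancellation to exactly zero
  vf <- cbind(v[, 1:2], 1)
  expect_equal(haplogen:::three_point_c(vf[, 1], vf[, 2], vf[, 3]), 0,
               tolerance = 1e-14)
  # invariance under joint 0<->1 relabeling with swapped allele arguments
  expect_equal(haplogen:::three_point_c(v[, 1], v[, 2], v[, 3], 1, 1, 1),
               haplogen:::three_point_c(1 - v[, 1], 1 - v[, 2], 1 - v[, 3],
                                        0, 0, 0),
               tolerance = 1e-14)
})

test_that("three-point summaries respect separations, seeds and skipping", {
  M <- random_hap(60, 40, seed = 7)
  out <- three_point_corr(M, separations = c(1, 4), n_triplets = 200,
                          seed = 8)
  expect_setequal(out$separation, c("1", "4", "random"))
  out2 <- three_point_corr(M, separations = c(1, 4), n_triplets = 200,
                           seed = 8)
  expect_identical(out, out2)   # seeded sampling reproduces bitwise
  expect_warning(three_point_corr(M, separations = c(64), n_triplets = 10,
                                  include_random = FALSE, seed = 1),
                 "too large")
  # independent sites: mean c stays within Monte-Carlo error of zero
  big <- random_hap(400, 30, seed = 9, p = rep(0.5, 30))
  res <- three_point_corr(big, separations = 1, n_triplets = 500,
                          include_random = FALSE, seed = 10)
  expect_lt(abs(res$mean_c), 3 * res$sd_c / sqrt(res$n_triplets) + 1e-3)
})

test_that("pairwise-distance distributions report the documented quantities", {
  real <- random_hap(12, 20, seed = 11)
  pw <- pairwise_distance_distributions(real, real)
  expect_equal(sum(pw$between == 0), 12)    # self-matches across the copy
  expect_equal(pw$wasserstein_within, 0)
  a <- haplotype_matrix(rbind(c(0, 0, 0, 0), c(1, 1, 1, 0)))
  expect_equal(pairwise_distance_distributions(a, a)$within_real, 3)
  # 1-D Wasserstein identities and a hand value
  expect_equal(wasserstein_1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein_1d(0, 5), 5)
  expect_equal(wasserstein_1d(c(0, 0), c(1, 3)), 2)  # mean sorted gap
})

test_that("nearest-neighbour profile handles copies, duplicates and nulls", {
  real <- random_hap(15, 25, seed = 12)
  nd <- nearest_neighbor_profile(real, real)
  expect_true(all(nd$d_ts == 0))
  dup <- haplotype_matrix(as.matrix(real)[c(1, 1, 2:15), ])
  nd2 <- suppressWarnings(nearest_neighbor_profile(dup, real))
  expect_equal(nd2$d_tt[1], 0)
  expect_error(nearest_neighbor_profile(haplotype_matrix(matrix(0:1, 1, 2)),
                                        real), "at least 2")
})

test_that("adversarial accuracy hits its forced endpoints exactly", {
  real <- random_hap(20, 30, seed = 13)
  # exact copy: strict inequality forces all three scores to 0
  aa0 <- adversarial_accuracy(nearest_neighbor_profile(real, real))
  expect_equal(c(aa0$aa_truth, aa0$aa_syn, aa0$aa_ts), c(0, 0, 0))
  # far-displaced artificial set: all three scores 1
  far <- haplotype_matrix(1 - as.matrix(real))
  aa1 <- adversarial_accuracy(nearest_neighbor_profile(real, far))
  expect_equal(c(aa1$aa_truth, aa1$aa_syn, aa1$aa_ts), c(1, 1, 1))
  # identity AA_TS = (AA_truth + AA_syn) / 2 on random pairs
  for (s in 1:5) {
    aa <- adversarial_accuracy(suppressWarnings(nearest_neighbor_profile(
      random_hap(10, 15, seed = s), random_hap(12, 15, seed = 100 + s))))
    expect_equal(aa$aa_ts, (aa$aa_truth + aa$aa_syn) / 2)
    expect_gte(aa$aa_ts, 0); expect_lte(aa$aa_ts, 1)
  }
  expect_warning(adversarial_accuracy(nearest_neighbor_profile(
    random_hap(5, 10, seed = 1), random_hap(7, 10, seed = 2))), "unequal")
})

test_that("privacy loss composes AA scores and is antisymmetric", {
  train <- random_hap(40, 30, seed = 14)
  test_set <- random_hap(40, 30, seed = 15)
  art <- random_hap(40, 30, seed = 16)
  pl <- privacy_loss(train, test_set, art)
  expect_equal(pl, aa_ts_score(test_set, art) - aa_ts_score(train, art))
  expect_equal(privacy_loss(test_set, train, art), -pl)
})

test_that("spike-in sensitivity reproduces its boundary cases", {
  train <- random_hap(30, 25, seed = 17)
  test_set <- random_hap(30, 25, seed = 18)
  art <- random_hap(30, 25, seed = 19)
  tab <- spike_in_sensitivity(train, test_set, art,
                              spike_counts = c(0, 30), seed = 20)
  base <- aa_ts_score(train, art)
  expect_equal(tab$aa_ts_train[tab$n_spiked == 0], base)
  # all rows replaced by training rows: the copy case (may sample duplicates,
  # so allow the duplicate-tie relaxation: score <= unspiked)
  expect_lte(tab$aa_ts_train[tab$n_spiked == 30], 0.1)
})

test_that("joint PCA returns one common embedding with PCA identities", {
  a <- random_hap(40, 20, seed = 21)
  pca <- joint_pca(list(one = a, two = a), n_components = 4)
  c1 <- as.matrix(pca[pca$dataset == "one", paste0("PC", 1:4)])
  c2 <- as.matrix(pca[pca$dataset == "two", paste0("PC", 1:4)])
  expect_equal(c1, c2)                      # duplicate datasets coincide
  ev <- attr(pca, "eigenvalues")
  scores <- rbind(c1, c2)
  expect_equal(sum(apply(scores, 2, var)), sum(ev), tolerance = 1e-10)
  M <- simulate_structured(seed = 22)
  p2 <- joint_pca(list(all = M), n_components = 2)
  expect_gt(silhouette_score(as.matrix(p2[, c("PC1", "PC2")]),
                             hap_labels(M)), 0)
})

test_that("entropic 2-D Wasserstein matches exact optimal transport", {
  # two single points: the only coupling costs d^2 whatever the regularisation
  expect_equal(wasserstein_2d(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 25,
               tolerance = 1e-8)
  # symmetry
  set.seed(23)
  a <- matrix(rnorm(40), 20); b <- matrix(rnorm(40) + 1, 20)
  expect_equal(wasserstein_2d(a, b), wasserstein_2d(b, a), tolerance = 1e-4)
  # identical clouds: residual entropic bias only
  expect_lt(wasserstein_2d(a, a), 1e-3)
  # small-regularisation limit against the exact assignment solution
  skip_if_not_installed("clue")
  C <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exact <- sum(C[cbind(seq_len(20), as.integer(clue::solve_LSAP(C)))]) / 20
  expect_equal(wasserstein_2d(a, b, reg = 1e-4), exact, tolerance = 0.02)
})

test_that("fixed-site report counts polymorphic-vs-fixed sites both ways", {
  real <- haplotype_matrix(rbind(c(0, 1, 1, 0), c(1, 1, 0, 0), c(0, 1, 1, 1)))
  expect_equal(sum(fixed_site_report(real, real)$count), 0)
  zeros <- haplotype_matrix(matrix(0L, 3, 4))
  rep0 <- fixed_site_report(real, zeros)
  # sites 1, 3, 4 are polymorphic in real; all fixed at 0 in art; site 2 is
  # fixed at 1 in real but fixed (0) in art, i.e. not counted as art-poly
  expect_equal(rep0$count[rep0$fixed_in == "art" & rep0$allele == 0], 3L)
  expect_equal(sum(rep0$count[rep0$fixed_in == "real"]), 0L)
  art <- haplotype_matrix(rbind(c(0, 1, 1, 1), c(0, 0, 1, 0), c(0, 1, 1, 0)))
  tab <- fixed_site_report(real, art)
  expect_equal(tab$count[tab$fixed_in == "art" & tab$allele == 0], 1L)
  expect_equal(tab$count[tab$fixed_in == "art" & tab$allele == 1], 1L)
})

test_that("metrics are invariant under row shuffles of either dataset", {
  real <- random_hap(25, 15, seed = 24)
  art <- random_hap(25, 15, seed = 25)
  set.seed(26)
  sh <- haplotype_matrix(as.matrix(art)[sample(25), ])
  expect_equal(allele_freq_comparison(real, sh)$correlation,
               allele_freq_comparison(real, art)$correlation)
  expect_equal(adversarial_accuracy(nearest_neighbor_profile(real, sh)),
               adversarial_accuracy(nearest_neighbor_profile(real, art)))
  expect_equal(sort(pairwise_distance_distributions(real, sh)$within_art),
               sort(pairwise_distance_distributions(real, art)$within_art))
})

test_that("evaluate_pair aggregates every metric once and reproduces bitwise", {
  real <- random_hap(40, 25, seed = 27)
  art <- random_hap(40, 25, seed = 28)
  r1 <- evaluate_pair(real, art, n_triplets = 100, separations = c(1, 4),
                      seed = 29)
  r2 <- evaluate_pair(real, art, n_triplets = 100, separations = c(1, 4),
                      seed = 29)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$three_point_real, r2$three_point_real)
  expect_named(r1$summary,
               c("freq_correlation", "ld_correlation", "wasserstein_pairwise",
                 "n_identical_pairs", "aa_truth", "aa_syn", "aa_ts",
                 "wasserstein_pca2d", "privacy_loss", "n_fixed_in_art"))
  # art = real: the degenerate values of the forced cases
  rr <- evaluate_pair(real, real, n_triplets = 50, separations = 1, seed = 30)
  expect_equal(rr$summary$freq_correlation, 1)
  expect_equal(rr$summary$aa_ts, 0)
  expect_equal(rr$summary$n_identical_pairs, 40)
  expect_equal(rr$summary$n_fixed_in_art, 0)
  expect_lt(rr$summary$wasserstein_pca2d, 1e-3)
  # privacy loss needs both splits
  expect_message(evaluate_pair(real, art, train = real, n_triplets = 10,
                               separations = 1, seed = 1),
                 "needs both")
})
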