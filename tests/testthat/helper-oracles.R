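# Shared fixtures and independent brute-force oracles used across the suite.
# The oracles deliberately avoid every code path of the package functions they
# check: plain loops, direct counting, closed forms.

random_hap <- function(n, L, seed = 1L, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(L, 0.1, 0.9)
  haplotype_matrix(matrix(rbinom(n * L, 1, rep(p, each = n)), n, L))
}

# Hamming distance by explicit looping
oracle_hamming <- function(a, b) sum(a != b)

oracle_cross_dist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    out[i, j] <- oracle_hamming(A[i, ], B[j, ])
  out
}

# nearest-neighbour AA statistics by explicit loops over the distance matrices
oracle_aa <- function(real, art) {
  vr <- as.matrix(real); va <- as.matrix(art)
  n <- nrow(vr); m <- nrow(va)
  cross <- oracle_cross_dist(vr, va)
  d_ts <- apply(cross, 1, min)
  d_st <- apply(cross, 2, min)
  d_tt <- vapply(seq_len(n), function(i)
    min(vapply(setdiff(seq_len(n), i), function(j)
      oracle_hamming(vr[i, ], vr[j, ]), numeric(1))), numeric(1))
  d_ss <- vapply(seq_len(m), function(i)
    min(vapply(setdiff(seq_len(m), i), function(j)
      oracle_hamming(va[i, ], va[j, ]), numeric(1))), numeric(1))
  at <- mean(d_ts > d_tt); as_ <- mean(d_st > d_ss)
  c(aa_truth = at, aa_syn = as_, aa_ts = (at + as_) / 2)
}

# squared Pearson correlation of two 0/1 columns from first principles
oracle_r2 <- function(x, y) {
  n <- length(x)
  cov <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  vx <- sum((x - mean(x))^2) / (n - 1)
  vy <- sum((y - mean(y))^2) / (n - 1)
  (cov / sqrt(vx * vy))^2
}

# connected 3-point moment by direct counting of the frequency terms
oracle_c3 <- function(x, y, z, a = 1, b = 1, cc = 1) {
  n <- length(x)
  fijk <- sum(x == a & y == b & z == cc) / n
  fij <- sum(x == a & y == b) / n
  fik <- sum(x == a & z == cc) / n
  fjk <- sum(y == b & z == cc) / n
  fi <- sum(x == a) / n; fj <- sum(y == b) / n; fk <- sum(z == cc) / n
  fijk - fij * fk - fik * fj - fjk * fi + 2 * fi * fj * fk
}

# Hudson-type two-population F_ST (ratio of averages over sites)
oracle_hudson_fst <- function(M) {
  lab <- hap_labels(M)
  pops <- unique(lab)
  stopifnot(length(pops) == 2)
  v <- as.matrix(M)
  p1 <- colMeans(v[lab == pops[1], , drop = FALSE])
  p2 <- colMeans(v[lab == pops[2], , drop = FALSE])
  n1 <- sum(lab == pops[1]); n2 <- sum(lab == pops[2])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# minimal phased VCF writer (the package only reads VCF, so this stays
# independent of the code under test)
write_toy_vcf <- function(M, path, chrom = "1", positions = NULL) {
  v <- as.matrix(M)
  stopifnot(nrow(v) %% 2 == 0)
  n_s <- nrow(v) / 2
  if (is.null(positions)) positions <- seq_len(ncol(v)) * 100
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", seq_len(n_s))),
                     collapse = "\t")), con)
  for (t in seq_len(ncol(v))) {
    gts <- vapply(seq_len(n_s), function(s)
      paste0(v[2 * s - 1, t], "|", v[2 * s, t]), character(1))
    writeLines(paste(c(chrom, positions[t], paste0("rs", t), "A", "G", ".",
                       "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  close(con)
  path
}

# mean silhouette width of labels on a 2-column embedding (cluster pkg)
silhouette_score <- function(coords, labels) {
  si <- cluster::silhouette(as.integer(factor(labels)), dist(coords))
  mean(si[, "sil_width"])
}
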