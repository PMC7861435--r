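#' Binary haplotype matrix
#'
#' The universal data container of the package: an `n_haplotypes x n_snps`
#' matrix of allele codes, 0 for the reference allele and 1 for the
#' alternative allele.  Rows are haplotypes (or, in the unphased genotype
#' layout, individuals with two columns per site), columns are SNPs.
#'
#' @param values integer/numeric matrix with entries in \{0, 1\}.
#' @param positions optional numeric vector of genomic coordinates (bp,
#'   1-based), one per SNP, strictly increasing.
#' @param snp_ids optional character vector of SNP identifiers.
#' @param labels optional per-row population/group labels.
#' @param phased logical; `TRUE` (default) means one column per site.  In the
#'   unphased layout columns pair up as (2t-1, 2t) for site t and the column
#'   count must be even.
#'
#' @return An object of class `haplotype_matrix`: the matrix itself with the
#'   metadata stored as attributes.
#' @examples
#' M <- haplotype_matrix(rbind(c(0, 1, 1), c(1, 1, 0)),
#'                       labels = c("POP1", "POP1"))
#' n_haplotypes(M)
#' allele_frequencies(M)
#' @export
haplotype_matrix <- function(values, positions = NULL, snp_ids = NULL,
                             labels = NULL, phased = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  obj <- structure(values,
                   positions = positions,
                   snp_ids = snp_ids,
                   labels = labels,
                   phased = isTRUE(phased),
                   class = c("haplotype_matrix", class(matrix())))
  validate_haplotype_matrix(obj)
}

#' Validate a haplotype matrix
#'
#' Checks the container invariants: entries all 0/1, at least one row and one
#' column, positions (if present) strictly increasing and one per SNP, labels
#' (if present) one per row, and an even column count in the unphased layout.
#'
#' @param M a `haplotype_matrix`.
#' @return `M`, invisibly unchanged, or an error describing the violation.
#' @export
validate_haplotype_matrix <- function(M) {
  v <- unclass(M)
  if (!is.matrix(v) || nrow(v) < 1L || ncol(v) < 1L)
    stop("haplotype matrix must have at least one row and one column",
         call. = FALSE)
  bad <- which(!(v == 0L | v == 1L) | is.na(v))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(v))
    stop(sprintf("non-binary allele code at row %d, column %d: %s",
                 i[1L], i[2L], as.character(v[bad[1L]])), call. = FALSE)
  }
  pos <- attr(M, "positions")
  if (!is.null(pos)) {
    if (length(pos) != ncol(v))
      stop("positions must have one entry per SNP", call. = FALSE)
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing", call. = FALSE)
  }
  ids <- attr(M, "snp_ids")
  if (!is.null(ids) && length(ids) != ncol(v))
    stop("snp_ids must have one entry per SNP", call. = FALSE)
  lab <- attr(M, "labels")
  if (!is.null(lab) && length(lab) != nrow(v))
    stop("labels must have one entry per haplotype", call. = FALSE)
  if (!isTRUE(attr(M, "phased")) && ncol(v) %% 2L != 0L)
    stop("unphased layout requires an even number of columns", call. = FALSE)
  M
}

#' @rdname haplotype_matrix
#' @param x,M a `haplotype_matrix`.
#' @export
n_haplotypes <- function(M) nrow(M)

#' @rdname haplotype_matrix
#' @export
n_snps <- function(M) {
  if (isTRUE(attr(M, "phased"))) ncol(M) else ncol(M) %/% 2L
}

#' @rdname haplotype_matrix
#' @export
hap_labels <- function(M) attr(M, "labels")

#' @rdname haplotype_matrix
#' @export
hap_positions <- function(M) attr(M, "positions")

#' Per-site alternative-allele frequencies
#'
#' @param M a `haplotype_matrix` (or plain 0/1 matrix).
#' @return numeric vector of column means, one per SNP column.
#' @export
allele_frequencies <- function(M) colMeans(hap_values(M))

# strip class/attributes down to a plain numeric matrix (internal currency)
hap_values <- function(M) {
  v <- unclass(M)
  attributes(v) <- list(dim = dim(v))
  storage.mode(v) <- "double"
  v
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix: %d haplotypes x %d columns (%s)>\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "phased"))) "phased, 1 column/site"
              else "unphased, 2 columns/site"))
  lab <- attr(x, "labels")
  if (!is.null(lab)) {
    tl <- table(lab)
    cat("  labels:", paste(sprintf("%s (%d)", names(tl), tl), collapse = ", "),
        "\n")
  }
  if (!is.null(attr(x, "positions")))
    cat(sprintf("  positions: %s..%s bp\n",
                format(min(attr(x, "positions"))),
                format(max(attr(x, "positions")))))
  k <- min(nrow(x), 5L); l <- min(ncol(x), 12L)
  print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE])
  if (nrow(x) > k || ncol(x) > l) cat("  ...\n")
  invisible(x)
}

#' @export
as.matrix.haplotype_matrix <- function(x, ...) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(v))
  v
}

# rebuild a haplotype_matrix carrying over metadata from a template
hap_like <- function(values, template = NULL, labels = NULL, phased = TRUE) {
  haplotype_matrix(values,
                   positions = if (!is.null(template)) attr(template, "positions"),
                   snp_ids = if (!is.null(template)) attr(template, "snp_ids"),
                   labels = labels,
                   phased = phased)
}

#' Split haplotypes into training and test subsets
#'
#' Row-wise random split at a given ratio (default 3:1 training:test, the
#' ratio used throughout for held-out evaluation).
#'
#' @param M a `haplotype_matrix`.
#' @param ratio training fraction in (0, 1); default 0.75.
#' @param seed integer seed for the permutation.
#' @return list with elements `train` and `test`, both `haplotype_matrix`.
#' @export
split_train_test <- function(M, ratio = 0.75, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- n_haplotypes(M)
  idx <- withr_seed(seed, sample.int(n))
  n_train <- max(1L, floor(n * ratio))
  if (n_train >= n) stop("split leaves no test haplotypes", call. = FALSE)
  lab <- hap_labels(M)
  take <- function(i) hap_like(unclass(M)[i, , drop = FALSE], M,
                               labels = if (!is.null(lab)) lab[i],
                               phased = attr(M, "phased"))
  list(train = take(idx[seq_len(n_train)]),
       test = take(idx[-seq_len(n_train)]))
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
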