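#' Read a plain-text haplotype ("hapt") file
#'
#' The hapt dialect is whitespace-separated text with one haplotype per row:
#' a group/population label token, a sample-id token, then one 0/1 token per
#' SNP.  An optional header line starting with `#` carries SNP identifiers.
#'
#' @param path file path.
#' @return a [haplotype_matrix()] with `labels` from the first token of each
#'   row; sample ids are kept as rownames.
#' @seealso [write_hapt()]
#' @export
read_hapt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  snp_ids <- NULL
  if (length(lines) && startsWith(trimws(lines[1L]), "#")) {
    hdr <- strsplit(trimws(sub("^\\s*#", "", lines[1L])), "\\s+")[[1L]]
    snp_ids <- hdr[nzchar(hdr)]
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("no data rows in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  if (length(unique(nt)) != 1L)
    stop(sprintf("ragged rows: line %d has %d tokens, line 1 has %d",
                 which(nt != nt[1L])[1L], nt[which(nt != nt[1L])[1L]], nt[1L]),
         call. = FALSE)
  if (nt[1L] < 3L)
    stop("each row needs a label, a sample id and at least one allele",
         call. = FALSE)
  labels <- vapply(toks, `[[`, character(1), 1L)
  ids <- vapply(toks, `[[`, character(1), 2L)
  allele <- lapply(toks, function(t) t[-(1:2)])
  for (r in seq_along(allele)) {
    bad <- which(!(allele[[r]] %in% c("0", "1")))
    if (length(bad))
      stop(sprintf("invalid allele token '%s' at line %d, column %d",
                   allele[[r]][bad[1L]], r, bad[1L]), call. = FALSE)
  }
  values <- do.call(rbind, lapply(allele, as.integer))
  rownames(values) <- ids
  haplotype_matrix(values, snp_ids = snp_ids, labels = labels)
}

#' Write a haplotype matrix to a hapt file
#'
#' @param M a [haplotype_matrix()].
#' @param path output file path.
#' @param labels,ids optional overrides for the label and sample-id columns;
#'   defaults come from the object (label "POP0" and "h<row>" when absent).
#' @return `path`, invisibly.
#' @export
write_hapt <- function(M, path, labels = NULL, ids = NULL) {
  M <- validate_haplotype_matrix(M)
  v <- unclass(M)
  n <- nrow(v)
  if (is.null(labels)) labels <- hap_labels(M)
  if (is.null(labels)) labels <- rep("POP0", n)
  if (is.null(ids)) ids <- rownames(v)
  if (is.null(ids)) ids <- paste0("h", seq_len(n))
  con <- file(path, open = "wb")  # binary mode forces Unix line endings
  on.exit(close(con))
  snp_ids <- attr(M, "snp_ids")
  if (!is.null(snp_ids))
    writeLines(paste("#", paste(snp_ids, collapse = " ")), con, sep = "\n")
  body <- paste(labels, ids,
                apply(v, 1L, paste, collapse = " "))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Extract phased haplotypes from a VCF
#'
#' Reads a VCF with phased genotypes (`GT` fields separated by `|`) at
#' biallelic sites and returns one row per haplotype: each sample contributes
#' two consecutive rows (left then right haplotype).  REF maps to 0, ALT to 1;
#' positions are the 1-based `POS` values as stored in the file.
#'
#' @param path VCF path (plain or bgzipped).
#' @param region optional `c(start, end)` coordinate window (bp, inclusive).
#' @param strict logical; if `TRUE` (default) an unphased genotype or a
#'   multiallelic site is an error.  If `FALSE`, unphased separators are
#'   accepted as written (force-genotype mode) and multiallelic sites are
#'   skipped with a message reporting the count.
#' @return a [haplotype_matrix()] with positions, SNP ids and rownames
#'   `<sample>_1` / `<sample>_2`.
#' @export
read_vcf_haplotypes <- function(path, region = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    keep <- pos >= region[1L] & pos <= region[2L]
    if (!any(keep)) stop("no sites in region", call. = FALSE)
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi & keep)) {
    if (strict)
      stop(sum(multi & keep), " multiallelic site(s) present (strict mode)",
           call. = FALSE)
    message("skipping ", sum(multi & keep), " multiallelic site(s)")
  }
  keep <- keep & !multi
  if (!any(keep)) stop("no biallelic sites to read", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  ids <- fix[keep, "ID"]
  if (any(is.na(gt))) stop("missing genotypes are not supported", call. = FALSE)
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased) && strict)
    stop("unphased genotype(s) found (use strict = FALSE to force)",
         call. = FALSE)
  samples <- colnames(gt)
  n_sites <- nrow(gt)
  values <- matrix(0L, nrow = 2L * length(samples), ncol = n_sites)
  for (s in seq_along(samples)) {
    parts <- strsplit(gt[, s], "[|/]")
    a <- vapply(parts, function(p) as.integer(p[1:2]), integer(2))
    if (any(is.na(a)) || any(a > 1L))
      stop("non-biallelic or missing allele in GT for sample ", samples[s],
           call. = FALSE)
    values[2L * s - 1L, ] <- a[1L, ]
    values[2L * s, ] <- a[2L, ]
  }
  rownames(values) <- as.vector(rbind(paste0(samples, "_1"),
                                      paste0(samples, "_2")))
  haplotype_matrix(values, positions = pos,
                   snp_ids = if (!all(is.na(ids))) ids)
}

#' Convert between haplotype and genotype (two-columns-per-site) layouts
#'
#' `to_genotype_layout()` folds consecutive row pairs (one individual's two
#' haplotypes) into single rows with two columns per site, interleaved
#' site-major: site t occupies columns (2t-1, 2t) holding the alleles of the
#' first and second chromosome.  `from_genotype_layout()` inverts it; the
#' composition is the identity.
#'
#' @param M a [haplotype_matrix()] (phased for `to_genotype_layout`, unphased
#'   for `from_genotype_layout`).
#' @return a [haplotype_matrix()] in the other layout.
#' @export
to_genotype_layout <- function(M) {
  M <- validate_haplotype_matrix(M)
  if (!isTRUE(attr(M, "phased")))
    stop("matrix is already in genotype layout", call. = FALSE)
  v <- unclass(M)
  if (nrow(v) %% 2L != 0L)
    stop("odd number of haplotypes: rows cannot be paired into individuals",
         call. = FALSE)
  n_ind <- nrow(v) %/% 2L
  L <- ncol(v)
  out <- matrix(0L, n_ind, 2L * L)
  out[, seq(1L, 2L * L, by = 2L)] <- v[seq(1L, nrow(v), by = 2L), , drop = FALSE]
  out[, seq(2L, 2L * L, by = 2L)] <- v[seq(2L, nrow(v), by = 2L), , drop = FALSE]
  lab <- hap_labels(M)
  haplotype_matrix(out,
                   labels = if (!is.null(lab)) lab[seq(1L, nrow(v), by = 2L)],
                   phased = FALSE)
}

#' @rdname to_genotype_layout
#' @export
from_genotype_layout <- function(M) {
  M <- validate_haplotype_matrix(M)
  if (isTRUE(attr(M, "phased")))
    stop("matrix is already in haplotype layout", call. = FALSE)
  v <- unclass(M)
  L <- ncol(v) %/% 2L
  out <- matrix(0L, 2L * nrow(v), L)
  out[seq(1L, nrow(out), by = 2L), ] <- v[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  out[seq(2L, nrow(out), by = 2L), ] <- v[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  lab <- hap_labels(M)
  haplotype_matrix(out,
                   labels = if (!is.null(lab)) rep(lab, each = 2L),
                   phased = TRUE)
}
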