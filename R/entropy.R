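#' Encode a joint genotype as a contingency-table row index
#'
#' Fixes the row order of the k-locus genotype-by-status table: the k
#' genotype codes are read as a mixed-radix (base 3) number with the first
#' SNP most significant, genotype order AA < Aa < aa (0 < 1 < 2). The map
#' is a bijection between genotype tuples and `0:(3^k - 1)`.
#'
#' @param codes integer vector of k genotype codes, each in \{0, 1, 2\}.
#' @return zero-based row index in `0:(3^k - 1)`.
#' @examples
#' encode_joint_genotype(c(2, 1))  # 2*3 + 1 = 7
#' decode_joint_genotype(7, k = 2)
#' @export
encode_joint_genotype <- function(codes) {
  codes <- as.integer(codes)
  if (anyNA(codes) || !all(codes %in% 0:2))
    stop("invalid genotype code: each code must be 0, 1 or 2")
  k <- length(codes)
  as.integer(sum(codes * 3^((k - 1L):0L)))
}

#' @rdname encode_joint_genotype
#' @param index zero-based row index.
#' @param k interaction order (number of SNPs).
#' @export
decode_joint_genotype <- function(index, k) {
  index <- as.integer(index)
  if (index < 0L || index >= 3L^k) stop("index out of range for order ", k)
  out <- integer(k)
  for (m in k:1) {
    out[m] <- index %% 3L
    index <- index %/% 3L
  }
  out
}

#' Genotype-by-status contingency table for a SNP combination
#'
#' Builds the `3^k x 2` table of joint-genotype counts against disease
#' status for one combination of k SNPs. Samples with a missing genotype at
#' any of the selected SNPs are excluded from this table only
#' (per-combination complete-case analysis).
#'
#' @param data a [genotype_data] object.
#' @param snps integer vector of k distinct SNP column indices, or SNP ids.
#' @return An object of class `rig_table`: an integer matrix with `3^k`
#'   rows (fixed mixed-radix genotype order, see [encode_joint_genotype])
#'   and columns `case`, `control`, with attributes `snp_indices`,
#'   `snp_ids`, `order`, `n_total` and `n_excluded`.
#' @export
contingency_table <- function(data, snps) {
  stopifnot(inherits(data, "genotype_data"))
  if (is.character(snps)) snps <- match(snps, data$snp_ids)
  snps <- as.integer(snps)
  p <- ncol(data$genotypes)
  if (anyNA(snps) || any(snps < 1L | snps > p)) stop("SNP index out of range")
  if (anyDuplicated(snps)) stop("SNP indices must be distinct")
  k <- length(snps)
  m <- 3L^k
  code <- joint_codes(data$genotypes, matrix(snps, ncol = 1L))[, 1L]
  ok <- !is.na(code)
  if (!any(ok)) stop("no samples with complete genotypes for this combination")
  y <- data$phenotype[ok]
  code <- code[ok]
  counts <- matrix(0L, nrow = m, ncol = 2L,
                   dimnames = list(joint_genotype_labels(k), c("case", "control")))
  counts[, 1L] <- tabulate(code[y == 1L] + 1L, nbins = m)
  counts[, 2L] <- tabulate(code[y == 0L] + 1L, nbins = m)
  structure(counts,
            snp_indices = snps,
            snp_ids = data$snp_ids[snps],
            order = k,
            n_total = sum(counts),
            n_excluded = sum(!ok),
            class = c("rig_table", "matrix", "array"))
}

# human-readable row labels "AA/Bb/..." for the fixed mixed-radix order
joint_genotype_labels <- function(k) {
  geno <- c("AA", "Aa", "aa")
  lab <- vapply(0:(3L^k - 1L), function(i)
    paste(geno[decode_joint_genotype(i, k) + 1L], collapse = "/"), character(1))
  lab
}

#' @export
print.rig_table <- function(x, ...) {
  cat("Genotype x status contingency table: ",
      paste(attr(x, "snp_ids"), collapse = ", "),
      " (order ", attr(x, "order"), ", n = ", attr(x, "n_total"), ")\n", sep = "")
  if (attr(x, "n_excluded") > 0L)
    cat("  excluded for missing genotypes: ", attr(x, "n_excluded"), "\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Shannon entropy of a count vector
#'
#' `-sum(p * log2(p))` over the non-zero cells of the empirical
#' distribution, in bits, with the `0 * log 0 = 0` convention.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(c(50, 50))  # 1 bit
#' shannon_entropy(c(75, 25))
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) stop("degenerate distribution: all counts are zero")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

as_count_matrix <- function(x) {
  if (inherits(x, "rig_table")) return(unclass(x))
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  stop("expected a contingency_table() result or a two-column count matrix")
}

#' Conditional entropy of disease status given joint genotype
#'
#' The row-weighted average of the per-genotype status entropies,
#' `sum(n_g / n * H(Y | X = g))`, in bits. Empty genotype rows contribute
#' zero, so sparse tables are handled without ambiguity.
#'
#' @param table a [contingency_table()] result, or any matrix with rows =
#'   X levels and two columns of case/control counts.
#' @return conditional entropy H(Y|X) in bits.
#' @export
conditional_entropy <- function(table) {
  tab <- as_count_matrix(table)
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  rowtot <- rowSums(tab)
  # sum over non-empty cells of a*log2(a/rowtot), zero rows drop out
  f <- function(a, t) {
    z <- a > 0
    sum(a[z] * log2(a[z] / t[z]))
  }
  -(f(tab[, 1L], rowtot) + f(tab[, 2L], rowtot)) / n
}

#' Relative information gain of a SNP combination
#'
#' The core association measure: information gain
#' `IG = H(Y) - H(Y|X)` between disease status Y and joint genotype X,
#' normalized by the phenotype entropy, `R0 = IG / H(Y)` (the normalized
#' mutual information). `R0` is 0 when the case proportion is identical in
#' every genotype row and 1 when every non-empty row is single-class.
#'
#' @param table a [contingency_table()] result or two-column count matrix.
#' @return An object of class `rig_result`: list with `snp_indices`,
#'   `snp_ids`, `order`, `H_Y`, `H_Y_given_X`, `IG` (bits) and `R0`.
#' @examples
#' tab <- rbind(c(30, 10), c(10, 30))
#' relative_information_gain(tab)
#' @export
relative_information_gain <- function(table) {
  tab <- as_count_matrix(table)
  H_Y <- shannon_entropy(colSums(tab))
  if (H_Y <= 0)
    stop("single-class table: both cases and controls are required (H(Y) = 0)")
  H_YX <- conditional_entropy(tab)
  IG <- H_Y - H_YX
  R0 <- IG / H_Y
  # clamp roundoff just outside [0, 1]
  R0 <- min(max(R0, 0), 1)
  structure(
    list(snp_indices = attr(table, "snp_indices"),
         snp_ids = attr(table, "snp_ids"),
         order = attr(table, "order") %||% log(nrow(tab), 3),
         H_Y = H_Y, H_Y_given_X = H_YX, IG = max(IG, 0), R0 = R0),
    class = "rig_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rig_result <- function(x, ...) {
  if (!is.null(x$snp_ids))
    cat("SNP combination: ", paste(x$snp_ids, collapse = ", "), "\n", sep = "")
  cat(sprintf("  H(Y) = %.6f bits, H(Y|X) = %.6f bits\n", x$H_Y, x$H_Y_given_X))
  cat(sprintf("  IG = %.6f bits, R0 = %.6f\n", x$IG, x$R0))
  invisible(x)
}

#' Likelihood-ratio (G-squared) independence statistic
#'
#' `G2 = 2 * sum(observed * ln(observed / expected))` over non-empty cells,
#' with expected counts from the row/column marginals. Numerically
#' identical to `2 * n * ln(2) * IG` when IG is measured in bits. Under
#' independence G2 is asymptotically chi-square with `3^k - 1` degrees of
#' freedom; the approximation degrades for sparse tables, so the count of
#' non-empty genotype rows is reported and a warning is issued when rows
#' are empty.
#'
#' @param table a [contingency_table()] result or two-column count matrix.
#' @param warn_sparse warn when some genotype rows are empty (default TRUE).
#' @return list with `G2`, `df` (`nrow - 1`), and `n_nonempty_rows`.
#' @export
g_statistic <- function(table, warn_sparse = TRUE) {
  tab <- as_count_matrix(table)
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  rowtot <- rowSums(tab)
  coltot <- colSums(tab)
  expected <- outer(rowtot, coltot) / n
  obs <- as.numeric(tab)
  exp <- as.numeric(expected)
  z <- obs > 0
  G2 <- 2 * sum(obs[z] * log(obs[z] / exp[z]))
  nonempty <- sum(rowtot > 0)
  df <- nrow(tab) - 1L
  if (warn_sparse && nonempty < nrow(tab))
    warning("sparse table: ", nrow(tab) - nonempty, " of ", nrow(tab),
            " genotype rows are empty; the chi-square approximation (df = ",
            df, ") may be poor")
  list(G2 = G2, df = df, n_nonempty_rows = nonempty)
}
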