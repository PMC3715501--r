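# Fast vectorized machinery for exhaustive order-k scans.
#
# joint_codes() maps each sample to its mixed-radix joint-genotype code for
# every combination at once; scan_r0_codes() then gets all R0 values for a
# phenotype vector with a single tabulate() pass, which is what makes the
# permutation ensemble affordable in pure R.

# G: n x p genotype matrix; combos: k x C matrix of column indices.
# Returns n x C integer matrix of codes 0..3^k-1, NA where any genotype is
# missing (per-combination complete-case exclusion).
joint_codes <- function(G, combos) {
  k <- nrow(combos)
  C <- ncol(combos)
  J <- matrix(0L, nrow(G), C)
  for (m in seq_len(k)) {
    J <- J * 3L + G[, combos[m, ], drop = FALSE]
  }
  J
}

# J: n x C joint codes (may contain NA); y: 0/1 phenotype; m = 3^k.
# Returns list(R0, IG, H_Y, H_YX), each length C.
scan_r0_codes <- function(J, y, m) {
  C <- ncol(J)
  code <- J * 2L + y                       # 0..2m-1; control even, case odd
  code <- code + rep.int(2L * m * (seq_len(C) - 1L), rep.int(nrow(J), C))
  cnt <- matrix(tabulate(code + 1L, nbins = 2L * m * C), nrow = 2L * m)
  ctrl <- cnt[seq.int(1L, 2L * m, by = 2L), , drop = FALSE]
  case <- cnt[seq.int(2L, 2L * m, by = 2L), , drop = FALSE]
  rowtot <- ctrl + case
  n0 <- .colSums(ctrl, m, C)
  n1 <- .colSums(case, m, C)
  N <- n0 + n1
  if (any(N == 0)) stop("a combination has no samples with complete genotypes")
  plogp <- function(x) {
    r <- numeric(length(x))
    z <- x > 0
    r[z] <- x[z] * log2(x[z])
    r
  }
  H_Y <- -(plogp(n0 / N) + plogp(n1 / N))
  xlx <- function(a, t) {
    r <- numeric(length(a))
    z <- a > 0
    r[z] <- a[z] * log2(a[z] / t[z])
    r
  }
  H_YX <- -.colSums(matrix(xlx(case, rowtot) + xlx(ctrl, rowtot), nrow = m), m, C) / N
  IG <- pmax(H_Y - H_YX, 0)
  R0 <- ifelse(H_Y > 0, pmin(IG / H_Y, 1), NA_real_)
  list(R0 = R0, IG = IG, H_Y = H_Y, H_YX = H_YX)
}

# All k-combinations of p SNPs, with a safety limit on the enumeration.
enumerate_combos <- function(p, k, max_combinations) {
  if (k < 1L || k > p) stop("order k must satisfy 1 <= k <= ", p)
  nc <- choose(p, k)
  if (nc > max_combinations)
    stop("refusing to scan ", format(nc, big.mark = ","), " combinations ",
         "(limit ", format(max_combinations, big.mark = ","),
         "); raise max_combinations to force")
  utils::combn(p, k)
}

#' Exhaustive relative-information-gain scan of all order-k combinations
#'
#' Computes the relative information gain R0 for every combination of `k`
#' SNPs and returns them ranked. Ranking is deterministic: R0 descending,
#' ties broken lexicographically on the SNP indices.
#'
#' @param data a [genotype_data] object.
#' @param order interaction order k (number of SNPs per combination).
#' @param top_n optionally keep only the strongest `top_n` combinations.
#' @param max_combinations safety limit on `choose(p, k)` (default 1e6);
#'   the scan refuses, stating the count, rather than silently grinding.
#' @return A data frame with one row per combination: `combo` (SNP ids,
#'   comma-separated), `R0`, `IG`, `H_Y`, `H_Y_given_X`, plus an
#'   `"indices"` attribute (k x C integer matrix aligned with the rows).
#' @seealso [rig_scan()] for the full scan + permutation-standardization
#'   pipeline.
#' @export
scan_rig <- function(data, order = 2L, top_n = NULL, max_combinations = 1e6) {
  stopifnot(inherits(data, "genotype_data"))
  check_two_classes(data)
  p <- ncol(data$genotypes)
  combos <- enumerate_combos(p, as.integer(order), max_combinations)
  res <- scan_combos(data, combos)
  ord <- rank_order(res$R0, combos)
  combos <- combos[, ord, drop = FALSE]
  out <- data.frame(
    combo = apply(combos, 2L, function(ix) paste(data$snp_ids[ix], collapse = ",")),
    R0 = res$R0[ord],
    IG = res$IG[ord],
    H_Y = res$H_Y[ord],
    H_Y_given_X = res$H_YX[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(top_n)) {
    keep <- seq_len(min(top_n, nrow(out)))
    out <- out[keep, , drop = FALSE]
    combos <- combos[, keep, drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "indices") <- combos
  attr(out, "order") <- as.integer(order)
  out
}

# scan a fixed combination set, chunked to bound memory for large C
scan_combos <- function(data, combos, chunk = 20000L) {
  k <- nrow(combos)
  m <- 3L^k
  C <- ncol(combos)
  res <- list(R0 = numeric(C), IG = numeric(C), H_Y = numeric(C), H_YX = numeric(C))
  for (start in seq.int(1L, C, by = chunk)) {
    ix <- start:min(start + chunk - 1L, C)
    J <- joint_codes(data$genotypes, combos[, ix, drop = FALSE])
    r <- scan_r0_codes(J, data$phenotype, m)
    for (nm in names(res)) res[[nm]][ix] <- r[[nm]]
  }
  res
}

# descending R0, ties lexicographic on SNP indices (deterministic scans)
rank_order <- function(R0, combos) {
  args <- c(list(-R0), lapply(seq_len(nrow(combos)), function(m) combos[m, ]))
  do.call(order, args)
}
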