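#' Permutation null distribution of the maximum relative information gain
#'
#' Builds the order-k null by repeatedly shuffling the phenotype labels
#' (genotypes fixed, case/control totals preserved) and recording, for each
#' permuted dataset, the maximum R0 over all k-combinations. One ensemble
#' per interaction order serves every combination of that order; its mean
#' and standard deviation standardize observed R0 values and its upper
#' quantile is the family-wise significance cutoff.
#'
#' @param data a [genotype_data] object.
#' @param order interaction order k.
#' @param n_perm number of permuted datasets (default 1000).
#' @param seed optional integer seed; the shuffles are drawn sequentially
#'   from this one stream, so a fixed seed reproduces the ensemble exactly.
#' @param max_combinations safety limit forwarded to the scan.
#' @return An object of class `rig_null`: list with `order`, `n_perm`, `M`
#'   (per-permutation maxima), `mu`, `sigma` (mean and unbiased sd of `M`),
#'   `n_combinations` and `seed`.
#' @examples
#' d <- simulate_case_control(n_snp = 4, n_sample = 80, seed = 1)
#' nul <- rig_null(d, order = 2, n_perm = 50, seed = 2)
#' nul
#' @export
rig_null <- function(data, order = 2L, n_perm = 1000L, seed = NULL,
                     max_combinations = 1e6) {
  stopifnot(inherits(data, "genotype_data"))
  check_two_classes(data)
  n_perm <- as.integer(n_perm)
  if (n_perm < 2L) stop("n_perm must be at least 2")
  order <- as.integer(order)
  combos <- enumerate_combos(ncol(data$genotypes), order, max_combinations)
  m <- 3L^order
  M <- numeric(n_perm)
  with_seed(seed, {
    # chunk the combination axis once, reusing the joint codes across all
    # permutations -- only the phenotype changes between shuffles
    C <- ncol(combos)
    chunk <- 20000L
    starts <- seq.int(1L, C, by = chunk)
    Js <- lapply(starts, function(s)
      joint_codes(data$genotypes, combos[, s:min(s + chunk - 1L, C), drop = FALSE]))
    for (i in seq_len(n_perm)) {
      y <- sample(data$phenotype)
      M[i] <- max(vapply(Js, function(J) max(scan_r0_codes(J, y, m)$R0), numeric(1)))
    }
  })
  mu <- mean(M)
  sigma <- stats::sd(M)
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate null: the permutation maxima have zero spread ",
         "(are all SNPs constant?)")
  structure(
    list(order = order, n_perm = n_perm, M = M, mu = mu, sigma = sigma,
         n_combinations = ncol(combos), seed = if (is.null(seed)) NA_integer_ else seed),
    class = "rig_null"
  )
}

#' @export
print.rig_null <- function(x, ...) {
  cat("Permutation null of the maximum R0 (order ", x$order, ")\n", sep = "")
  cat(sprintf("  %d permutations over %d combinations\n", x$n_perm, x$n_combinations))
  cat(sprintf("  mu = %.6f, sigma = %.6f\n", x$mu, x$sigma))
  q <- stats::quantile(x$M, c(0.5, 0.95, 0.99), names = FALSE)
  cat(sprintf("  M quantiles: 50%% %.4f, 95%% %.4f, 99%% %.4f\n", q[1], q[2], q[3]))
  invisible(x)
}

#' Family-wise significance cutoff from a permutation null
#'
#' The level-`alpha` cutoff is the empirical upper-`alpha` order statistic
#' of the permutation maxima: the `ceiling((1 - alpha) * n_perm)`-th
#' smallest element of M (a conservative convention for small ensembles).
#' A combination is declared significant iff its observed `R0 > M_cut`,
#' equivalently its standardized score `U_r > U_cut`.
#'
#' @param null a [rig_null] object.
#' @param alpha significance level in (0, 1) with `n_perm * alpha >= 1`.
#' @return list with `M_cut`, `U_cut` and `alpha`.
#' @export
rig_cutoff <- function(null, alpha = 0.05) {
  stopifnot(inherits(null, "rig_null"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be strictly between 0 and 1")
  if (null$n_perm * alpha < 1)
    stop("n_perm * alpha < 1: the ensemble cannot resolve level ", alpha)
  M_cut <- sort(null$M)[ceiling((1 - alpha) * null$n_perm)]
  list(M_cut = M_cut, U_cut = (M_cut - null$mu) / null$sigma, alpha = alpha)
}

#' Permutation-adjusted p-value for an observed R0
#'
#' The fraction of permutation maxima at least as large as the observed
#' value, `#\{i : M_i >= R0\} / n_perm` -- a max-statistic adjustment that
#' controls the family-wise error rate across all combinations of the
#' null's order. A count of zero is stored as the number 0 and rendered as
#' `< 1/n_perm` in printed reports.
#'
#' @param R0 numeric vector of observed relative information gains.
#' @param null a [rig_null] object of the matching order.
#' @return numeric vector of adjusted p-values in \[0, 1\].
#' @export
adjusted_pvalue <- function(R0, null) {
  stopifnot(inherits(null, "rig_null"))
  vapply(R0, function(r) mean(null$M >= r), numeric(1))
}

format_pvalue <- function(p, n_perm) {
  ifelse(p == 0, paste0("< ", format(1 / n_perm, digits = 3)),
         format(p, digits = 3))
}

#' Standardize scan results against a permutation null
#'
#' Converts each observed R0 into the standardized relative information
#' gain `U_r = (R0 - mu) / sigma`, where mu and sigma come from the
#' matching-order null of maximum R0s, and attaches the adjusted p-value.
#' Standardization is a monotone transform, so the ranking by `U_r` is the
#' ranking by `R0`; its purpose is comparability across interaction orders,
#' whose raw R0 scales differ.
#'
#' @param results a [scan_rig()] data frame.
#' @param null a [rig_null] of the same order.
#' @return the input data frame with `U_r` and `p_adj` columns appended,
#'   row order preserved.
#' @export
standardize_rig <- function(results, null) {
  stopifnot(is.data.frame(results), inherits(null, "rig_null"))
  ord <- attr(results, "order")
  if (!is.null(ord) && ord != null$order)
    stop("order mismatch: scan is order ", ord, " but null is order ", null$order)
  results$U_r <- (results$R0 - null$mu) / null$sigma
  results$p_adj <- adjusted_pvalue(results$R0, null)
  results
}

#' Export / import a permutation-null summary as JSON
#'
#' Stores the order, ensemble size, mean, standard deviation, selected
#' quantiles and seed -- and by default the full vector of maxima -- so
#' that later scans can be re-standardized without re-permuting.
#'
#' @param null a [rig_null] object.
#' @param path output JSON path.
#' @param include_draws store the full `M` vector (default TRUE; required
#'   for adjusted p-values and cutoffs on re-import).
#' @return `write_null_json` returns `path` invisibly; `read_null_json`
#'   returns a [rig_null] object (without `M` if draws were not stored).
#' @export
write_null_json <- function(null, path, include_draws = TRUE) {
  stopifnot(inherits(null, "rig_null"))
  obj <- list(
    order = null$order, n_perm = null$n_perm,
    mu = null$mu, sigma = null$sigma,
    quantiles = as.list(stats::quantile(null$M, c(0.5, 0.9, 0.95, 0.99))),
    n_combinations = null$n_combinations,
    seed = null$seed
  )
  if (include_draws) obj$M <- null$M
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_null_json
#' @export
read_null_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(order = as.integer(obj$order), n_perm = as.integer(obj$n_perm),
         M = obj$M, mu = obj$mu, sigma = obj$sigma,
         n_combinations = obj$n_combinations,
         seed = if (is.null(obj$seed)) NA_integer_ else obj$seed),
    class = "rig_null"
  )
}
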