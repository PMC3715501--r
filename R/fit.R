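#' Fit a standardized relative-information-gain interaction scan
#'
#' The main entry point: exhaustively scores every order-`k` SNP
#' combination by relative information gain, builds the permutation null
#' of the per-dataset maximum R0 for that order, standardizes the observed
#' values (`U_r = (R0 - mu) / sigma`), attaches family-wise adjusted
#' p-values and the level-`alpha` significance cutoff.
#'
#' The procedure is the four-stage entropy pipeline: (i) a `3^k x 2`
#' genotype-by-status contingency table per combination, (ii) initial
#' relative information gain `R0 = (H(Y) - H(Y|X)) / H(Y)`, (iii)
#' standardization against the permutation-max null, which both controls
#' the family-wise error rate and makes scores comparable across
#' interaction orders (raw R0 inflates mechanically with order), and (iv)
#' scree/MDS visualization via [plot.rig_scan()] and [mds_plot()].
#'
#' @param data a [genotype_data] object.
#' @param order interaction order k (default 2).
#' @param n_perm size of the permutation ensemble (default 1000).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed optional integer seed making the permutation ensemble (and
#'   hence `U_r`, p-values and cutoffs) exactly reproducible.
#' @param top_n number of top combinations retained in the results table
#'   (default 100, matching the scree-plot convention); `NULL` keeps all.
#' @param max_combinations safety limit on `choose(p, k)`.
#' @return An object of class `rig_scan`: list with `results` (ranked data
#'   frame: `combo`, `R0`, `IG`, `H_Y`, `H_Y_given_X`, `U_r`, `p_adj`),
#'   `null` ([rig_null]), `cutoff` (`M_cut`, `U_cut`, `alpha`),
#'   `n_significant` (count over all combinations, not just the retained
#'   top), `order`, `n_perm`, `seed`, `data_digest`, `call`.
#' @examples
#' d <- simulate_case_control(n_snp = 6, n_sample = 200, model = 1, seed = 1)
#' fit <- rig_scan(d, order = 2, n_perm = 100, seed = 2)
#' fit
#' coef(fit)[1:3]
#' @export
rig_scan <- function(data, order = 2L, n_perm = 1000L, alpha = 0.05,
                     seed = NULL, top_n = 100L, max_combinations = 1e6) {
  stopifnot(inherits(data, "genotype_data"))
  check_two_classes(data)
  cl <- match.call()
  scan <- scan_rig(data, order = order, top_n = NULL,
                   max_combinations = max_combinations)
  null <- rig_null(data, order = order, n_perm = n_perm, seed = seed,
                   max_combinations = max_combinations)
  scan <- standardize_rig(scan, null)
  cut <- rig_cutoff(null, alpha)
  n_sig <- sum(scan$R0 > cut$M_cut)
  if (!is.null(top_n) && nrow(scan) > top_n) {
    ix <- attr(scan, "indices")
    ord <- attr(scan, "order")
    scan <- scan[seq_len(top_n), , drop = FALSE]
    attr(scan, "indices") <- ix[, seq_len(top_n), drop = FALSE]
    attr(scan, "order") <- ord
  }
  structure(
    list(results = scan, null = null, cutoff = cut, n_significant = n_sig,
         order = as.integer(order), n_perm = as.integer(n_perm),
         alpha = alpha,
         seed = if (is.null(seed)) NA_integer_ else seed,
         data_digest = list(
           n_samples = nrow(data$genotypes), n_snps = ncol(data$genotypes),
           n_cases = sum(data$phenotype == 1L),
           n_controls = sum(data$phenotype == 0L),
           n_missing = sum(is.na(data$genotypes))),
         call = cl),
    class = "rig_scan"
  )
}

#' @export
print.rig_scan <- function(x, n = 5L, ...) {
  d <- x$data_digest
  cat("Standardized relative-information-gain scan (order ", x$order, ")\n", sep = "")
  cat(sprintf("  data: %d samples (%d cases / %d controls), %d SNPs\n",
              d$n_samples, d$n_cases, d$n_controls, d$n_snps))
  cat(sprintf("  null: %d permutations; mu = %.5f, sigma = %.5f\n",
              x$n_perm, x$null$mu, x$null$sigma))
  cat(sprintf("  cutoff (alpha = %g): M_cut = %.5f, U_cut = %.3f; %d significant\n",
              x$cutoff$alpha, x$cutoff$M_cut, x$cutoff$U_cut, x$n_significant))
  n <- min(n, nrow(x$results))
  top <- x$results[seq_len(n), c("combo", "R0", "U_r", "p_adj")]
  top$p_adj <- format_pvalue(top$p_adj, x$n_perm)
  cat("  top combinations:\n")
  print(top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rig_scan <- function(object, ...) {
  structure(list(fit = object), class = "summary.rig_scan")
}

#' @export
print.summary.rig_scan <- function(x, ...) {
  f <- x$fit
  print(f, n = 10L)
  q <- stats::quantile(f$null$M, c(0.5, 0.9, 0.95, 0.99))
  cat("  null M quantiles:\n")
  print(round(q, 5))
  sig <- f$results[f$results$R0 > f$cutoff$M_cut, "combo"]
  if (length(sig))
    cat("  significant (within retained top):", paste(sig, collapse = "; "), "\n")
  else cat("  no combination exceeds the cutoff\n")
  invisible(x)
}

#' Extract interaction scores from a fitted scan
#'
#' @param object a [rig_scan] fit.
#' @param measure `"U_r"` (standardized, default) or `"R0"` (raw).
#' @param ... unused.
#' @return named numeric vector, names are the SNP combinations, in rank
#'   order.
#' @export
coef.rig_scan <- function(object, measure = c("U_r", "R0"), ...) {
  measure <- match.arg(measure)
  stats::setNames(object$results[[measure]], object$results$combo)
}

#' Scree plot of a fitted interaction scan
#'
#' Plots the ranked scores (standardized `U_r` by default, raw `R0` on
#' request) against their rank, with the family-wise cutoff as a dotted
#' horizontal line and the top-ranked combination labelled in parentheses.
#' The "last substantial drop" (elbow) is left to visual judgment; the
#' number of combinations above the cutoff line is reported by the fit.
#'
#' @param x a [rig_scan] fit.
#' @param measure `"U_r"` or `"R0"`.
#' @param top_n number of top-ranked points drawn (default 100; clamped to
#'   the number of available results).
#' @param file optional path; when given, the figure is written as PNG (or
#'   SVG if the extension is `.svg`) instead of drawn on the active device.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of plotted points (`rank`, `combo`,
#'   score, cutoff) -- the machine-readable twin of the figure.
#' @export
plot.rig_scan <- function(x, measure = c("U_r", "R0"), top_n = 100L,
                          file = NULL, ...) {
  measure <- match.arg(measure)
  cutoff <- if (measure == "U_r") x$cutoff$U_cut else x$cutoff$M_cut
  scree_plot(x$results, cutoff = cutoff, measure = measure,
             top_n = top_n, file = file, ...)
}
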