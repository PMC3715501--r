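open_device <- function(file, width = 7, height = 5) {
  if (is.null(file)) return(FALSE)
  if (grepl("\\.svg$", file, ignore.case = TRUE))
    grDevices::svg(file, width = width, height = height)
  else grDevices::png(file, width = width * 120, height = height * 120, res = 120)
  TRUE
}

#' Scree plot of ranked interaction scores
#'
#' Plots scores against their rank (strongest first, hence a
#' non-increasing series), draws the family-wise cutoff as a dotted
#' horizontal line, and labels the top-ranked SNP combination in
#' parentheses. Usually called through [plot.rig_scan()].
#'
#' @param results data frame with a `combo` column and the score column
#'   named by `measure` (a [scan_rig()] / [rig_scan()] results table).
#' @param cutoff optional cutoff value for the dotted line (on the scale
#'   of `measure`).
#' @param measure score column to plot, `"U_r"` or `"R0"`.
#' @param top_n number of top-ranked points (clamped to what is
#'   available; default 100).
#' @param file optional output path (PNG, or SVG by extension); `NULL`
#'   draws on the current device.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted points as a data frame (`rank`,
#'   `combo`, score, and the cutoff as an attribute) -- the
#'   machine-readable twin of the figure.
#' @export
scree_plot <- function(results, cutoff = NULL, measure = c("U_r", "R0"),
                       top_n = 100L, file = NULL, ...) {
  measure <- match.arg(measure)
  if (!nrow(results)) stop("no results to plot")
  if (!measure %in% names(results))
    stop("results have no '", measure, "' column (standardize first?)")
  y <- results[[measure]]
  ord <- order(-y)
  keep <- ord[seq_len(min(top_n, length(y)))]
  pts <- data.frame(rank = seq_along(keep), combo = results$combo[keep],
                    value = y[keep], stringsAsFactors = FALSE)
  names(pts)[3L] <- measure
  dev <- open_device(file)
  if (dev) on.exit(grDevices::dev.off())
  ylab <- if (measure == "U_r") "standardized relative information gain (U_r)"
          else "relative information gain (R0)"
  graphics::plot(pts$rank, pts[[measure]], xlab = "rank", ylab = ylab,
                 pch = 19, cex = 0.6, ...)
  if (!is.null(cutoff)) graphics::abline(h = cutoff, lty = 3)
  graphics::text(1, pts[[measure]][1L], labels = paste0("(", pts$combo[1L], ")"),
                 pos = 4, cex = 0.8)
  attr(pts, "cutoff") <- cutoff
  invisible(pts)
}

#' Pairwise and single-locus relative information gain
#'
#' Convenience wrapper assembling the inputs of [mds_plot()]: the
#' symmetric `p x p` matrix of two-locus R0 values (zero diagonal) and
#' the length-`p` vector of single-locus (main effect) R0 values.
#'
#' @param data a [genotype_data] object.
#' @param max_combinations forwarded to the scans.
#' @return list with `pairwise` (matrix) and `main_effect` (named vector).
#' @export
pairwise_rig <- function(data, max_combinations = 1e6) {
  stopifnot(inherits(data, "genotype_data"))
  p <- ncol(data$genotypes)
  s2 <- scan_rig(data, order = 2L, max_combinations = max_combinations)
  ix <- attr(s2, "indices")
  M <- matrix(0, p, p, dimnames = list(data$snp_ids, data$snp_ids))
  for (j in seq_len(ncol(ix))) {
    M[ix[1L, j], ix[2L, j]] <- s2$R0[j]
    M[ix[2L, j], ix[1L, j]] <- s2$R0[j]
  }
  s1 <- scan_rig(data, order = 1L, max_combinations = max_combinations)
  main <- numeric(p)
  main[attr(s1, "indices")[1L, ]] <- s1$R0
  list(pairwise = M, main_effect = stats::setNames(main, data$snp_ids))
}

#' MDS map of two-locus interactions
#'
#' Applies classical (Torgerson) multidimensional scaling to the matrix
#' of pairwise interaction strengths, so the plotted distance between two
#' SNPs approximates the strength of their two-locus interaction; point
#' sizes grow affinely with each SNP's single-locus (main effect) R0, so
#' first- and second-order effects are read off one figure. The default
#' distance entry is the pairwise R0 itself; `measure = "U_shifted"`
#' instead uses standardized scores shifted by a positive constant
#' (`-min(U)`) so all distances are non-negative, which yields an
#' equivalent configuration.
#'
#' @param pairwise symmetric non-negative `p x p` matrix with zero
#'   diagonal: two-locus R0 values, or U_r values when
#'   `measure = "U_shifted"` (the shift is applied internally).
#' @param main_effect optional length-`p` vector of single-locus R0
#'   values driving point sizes.
#' @param measure `"R0"` (use the matrix as-is) or `"U_shifted"` (add
#'   `-min` so the smallest entry becomes zero).
#' @param file optional figure path (PNG/SVG); a sidecar
#'   `<file>_coords.tsv` with the embedded coordinates is written next to
#'   it.
#' @param cex_range marker size range mapped affinely onto
#'   `main_effect`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data frame of SNP coordinates (and `main_effect`
#'   when supplied).
#' @export
mds_plot <- function(pairwise, main_effect = NULL,
                     measure = c("R0", "U_shifted"), file = NULL,
                     cex_range = c(0.8, 3), ...) {
  measure <- match.arg(measure)
  D <- as.matrix(pairwise)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("pairwise matrix must be square and symmetric")
  if (any(diag(D) != 0)) stop("pairwise matrix must have a zero diagonal")
  if (measure == "U_shifted") {
    off <- D[upper.tri(D)]
    shift <- -min(off)
    D[upper.tri(D) | lower.tri(D)] <- D[upper.tri(D) | lower.tri(D)] + shift
  }
  if (any(D < 0)) stop("distances must be non-negative")
  p <- nrow(D)
  ids <- rownames(D) %||% paste0("SNP", seq_len(p))
  mds <- stats::cmdscale(stats::as.dist(D), k = min(2L, p - 1L), eig = TRUE)
  npos <- sum(mds$eig > sqrt(.Machine$double.eps))
  if (npos < 2L) {
    warning("fewer than 2 positive eigenvalues; falling back to a 1-D layout")
    coords <- cbind(mds$points[, 1L], 0)
  } else {
    coords <- mds$points[, 1:2, drop = FALSE]
  }
  colnames(coords) <- c("dim1", "dim2")
  cex <- rep(1.5, p)
  if (!is.null(main_effect)) {
    stopifnot(length(main_effect) == p)
    rng <- range(main_effect)
    cex <- if (diff(rng) > 0)
      cex_range[1L] + (main_effect - rng[1L]) / diff(rng) * diff(cex_range)
    else rep(mean(cex_range), p)
  }
  dev <- open_device(file, width = 6, height = 6)
  if (dev) on.exit(grDevices::dev.off())
  graphics::plot(coords, cex = cex, pch = 21, bg = "grey70",
                 xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  graphics::text(coords, labels = ids, pos = 3, cex = 0.75)
  out <- data.frame(snp = ids, coords, stringsAsFactors = FALSE)
  if (!is.null(main_effect)) out$main_effect <- as.numeric(main_effect)
  if (!is.null(file)) {
    sidecar <- paste0(sub("\\.[A-Za-z]+$", "", file), "_coords.tsv")
    utils::write.table(out, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
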