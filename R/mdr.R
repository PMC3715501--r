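# Multifactor dimensionality reduction (MDR) baseline: genotype cells are
# pooled into "high risk" / "low risk" by their case:control ratio and a
# SNP combination is scored by the balanced accuracy of that two-level
# classifier under stratified cross-validation.

#' Classify genotype cells as high or low risk
#'
#' A cell is high-risk iff its case/control ratio is at least `threshold`
#' (default: the table's overall case:control ratio, i.e. the training
#' fold's ratio in cross-validation). A cell with cases but no controls is
#' high-risk; an empty cell is low-risk.
#'
#' @param table a [contingency_table()] result or two-column (case,
#'   control) count matrix.
#' @param threshold positive ratio threshold; default
#'   `sum(cases) / sum(controls)`.
#' @return logical vector over the `3^k` cells; `TRUE` = high risk.
#' @export
classify_cells <- function(table, threshold = NULL) {
  tab <- as_count_matrix(table)
  case <- tab[, 1L]; ctrl <- tab[, 2L]
  if (is.null(threshold)) threshold <- sum(case) / sum(ctrl)
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  case >= threshold * ctrl & (case + ctrl) > 0
}

#' Balanced accuracy of a high/low risk labelling
#'
#' Treats a high-risk prediction as "case": sensitivity is the fraction of
#' cases falling in high-risk cells, specificity the fraction of controls
#' in low-risk cells, and the score is their mean.
#'
#' @param risk_labels logical vector over cells (`TRUE` = high risk).
#' @param table the evaluation table (same cell order), with both classes
#'   present.
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(risk_labels, table) {
  tab <- as_count_matrix(table)
  stopifnot(length(risk_labels) == nrow(tab))
  n1 <- sum(tab[, 1L]); n0 <- sum(tab[, 2L])
  if (n1 == 0 || n0 == 0) stop("evaluation table must contain both classes")
  sens <- sum(tab[risk_labels, 1L]) / n1
  spec <- sum(tab[!risk_labels, 2L]) / n0
  (sens + spec) / 2
}

# vectorized cell classification + BA over C combinations at once.
# case/ctrl: m x C count matrices; returns list(high = m x C logical,
# ba = length-C balanced accuracies against (ecase, ectrl)).
mdr_ba_matrix <- function(case, ctrl, thr, ecase = case, ectrl = ctrl) {
  high <- case >= thr * ctrl & (case + ctrl) > 0
  n1 <- colSums(ecase); n0 <- colSums(ectrl)
  sens <- colSums(ecase * high) / n1
  spec <- colSums(ectrl * !high) / n0
  list(high = high, ba = (sens + spec) / 2)
}

fold_counts <- function(code1, code0, rows1, rows0, m, C) {
  # code1/code0: case/control joint codes offset per combination column
  list(case = matrix(tabulate(code1[rows1, ], nbins = m * C), nrow = m),
       ctrl = matrix(tabulate(code0[rows0, ], nbins = m * C), nrow = m))
}

#' Cross-validated multifactor dimensionality reduction scan
#'
#' Evaluates every order-`k` SNP combination by MDR: within each of
#' `folds` phenotype-stratified cross-validation folds, cells are
#' labelled high/low risk on the training split (threshold = training
#' case:control ratio) and the labelling is scored by balanced accuracy
#' on both splits. The combination with the best training balanced
#' accuracy is selected in each fold; cross-validation consistency (CVC)
#' counts how often each combination is selected. The overall winner has
#' maximal CVC, ties broken by mean testing balanced accuracy, then
#' lexicographically.
#'
#' @param data a [genotype_data] object.
#' @param order combination order k (default 2).
#' @param folds number of cross-validation folds (default 10).
#' @param repeats repeats of the whole cross-validation (default 1); with
#'   repeats > 1 the reported CVC is the average selection count per
#'   repeat.
#' @param seed optional integer seed fixing the fold assignment.
#' @param max_combinations safety limit on `choose(p, k)`.
#' @return An object of class `mdr_cv`: list with `results` (data frame
#'   ranked by CVC: `combo`, `train_ba`, `test_ba`, `cvc`, plus an
#'   `"indices"` attribute), `winner` (top row), `risk_labels` (winner's
#'   high/low cells fitted on the full data), `order`, `folds`, `repeats`,
#'   `seed`.
#' @examples
#' d <- simulate_case_control(n_snp = 6, n_sample = 400, model = 1, seed = 1)
#' mdr_cv(d, order = 2, seed = 2)
#' @export
mdr_cv <- function(data, order = 2L, folds = 10L, repeats = 1L, seed = NULL,
                   max_combinations = 1e5) {
  stopifnot(inherits(data, "genotype_data"))
  check_two_classes(data)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  order <- as.integer(order)
  combos <- enumerate_combos(ncol(data$genotypes), order, max_combinations)
  C <- ncol(combos)
  m <- 3L^order
  idx1 <- which(data$phenotype == 1L)
  idx0 <- which(data$phenotype == 0L)
  if (min(length(idx1), length(idx0)) < folds)
    stop("each class needs at least one sample per fold")
  J <- joint_codes(data$genotypes, combos)
  off <- rep.int(m * (seq_len(C) - 1L), rep.int(nrow(J), C))
  codeoff <- J + off + 1L   # NA where genotypes missing; tabulate drops NA
  sel <- integer(C)
  train_sum <- numeric(C)
  test_sum <- numeric(C)
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      f1 <- sample(rep_len(seq_len(folds), length(idx1)))
      f0 <- sample(rep_len(seq_len(folds), length(idx0)))
      for (fold in seq_len(folds)) {
        tr1 <- idx1[f1 != fold]; te1 <- idx1[f1 == fold]
        tr0 <- idx0[f0 != fold]; te0 <- idx0[f0 == fold]
        tr <- fold_counts(codeoff, codeoff, tr1, tr0, m, C)
        te <- fold_counts(codeoff, codeoff, te1, te0, m, C)
        thr <- length(tr1) / length(tr0)
        fit <- mdr_ba_matrix(tr$case, tr$ctrl, thr)
        test_ba <- mdr_ba_matrix(tr$case, tr$ctrl, thr, te$case, te$ctrl)$ba
        best <- which.max(fit$ba)  # first max = lexicographic tie-break
        sel[best] <- sel[best] + 1L
        train_sum <- train_sum + fit$ba
        test_sum <- test_sum + test_ba
      }
    }
  })
  n_eval <- folds * repeats
  cvc <- sel / repeats
  res <- data.frame(
    combo = apply(combos, 2L, function(ix) paste(data$snp_ids[ix], collapse = ",")),
    train_ba = train_sum / n_eval,
    test_ba = test_sum / n_eval,
    cvc = cvc,
    stringsAsFactors = FALSE
  )
  args <- c(list(-res$cvc, -res$test_ba),
            lapply(seq_len(order), function(mm) combos[mm, ]))
  ord <- do.call(base::order, args)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  combos <- combos[, ord, drop = FALSE]
  attr(res, "indices") <- combos
  win_tab <- contingency_table(data, combos[, 1L])
  structure(
    list(results = res, winner = res[1L, ],
         risk_labels = classify_cells(win_tab),
         order = order, folds = folds, repeats = as.integer(repeats),
         seed = if (is.null(seed)) NA_integer_ else seed),
    class = "mdr_cv"
  )
}

#' @export
print.mdr_cv <- function(x, n = 5L, ...) {
  cat("MDR cross-validation scan (order ", x$order, ", ", x$folds,
      "-fold", if (x$repeats > 1L) paste0(" x ", x$repeats, " repeats"),
      ")\n", sep = "")
  cat("  winner: ", x$winner$combo,
      sprintf("  (CVC %.1f, test BA %.4f)\n", x$winner$cvc, x$winner$test_ba), sep = "")
  print(utils::head(x$results, n), digits = 4, row.names = FALSE)
  invisible(x)
}

# best pair under a selection criterion; returns SNP indices
mdr_top_pair <- function(mdr, criterion = c("CVC", "BA")) {
  criterion <- match.arg(criterion)
  res <- mdr$results
  ix <- attr(res, "indices")
  if (criterion == "CVC") return(ix[, 1L])
  args <- c(list(-res$test_ba), lapply(seq_len(nrow(ix)), function(m) ix[m, ]))
  ix[, do.call(order, args)[1L]]
}
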