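# Two-locus disease models used by the power simulations. Each model is a
# 3x3 grid of genotype odds ratios (rows: locus B genotypes BB/Bb/bb,
# columns: locus A genotypes AA/Aa/aa), a shared minor allele frequency
# for the two causal loci, and a target population prevalence. Models 1-3
# vary effect size at fixed structure; 4-6 and 7-8 are interaction
# patterns with little marginal effect taken from the MDR literature.
or_grid <- function(v) matrix(v, 3, 3, byrow = TRUE,
                              dimnames = list(c("BB", "Bb", "bb"), c("AA", "Aa", "aa")))

two_locus_models <- list(
  list(or = or_grid(c(1.21, 0.2, 0.2,   0.2, 5, 5,      0.2, 5, 5)),
       maf = 0.1, prevalence = 0.050),
  list(or = or_grid(c(1.23, 0.33, 0.33, 0.33, 3, 3,     0.33, 3, 3)),
       maf = 0.1, prevalence = 0.050),
  list(or = or_grid(c(1.22, 0.4, 0.4,   0.4, 2.5, 2.5,  0.4, 2.5, 2.5)),
       maf = 0.1, prevalence = 0.050),
  list(or = or_grid(c(0.55, 1.75, 1.33, 1.54, 0.18, 0.74, 1.75, 0.18, 0)),
       maf = 0.1, prevalence = 0.046),
  list(or = or_grid(c(1.16, 0.38, 0.76, 0.38, 3.70, 1.97, 0.76, 1.97, 2.82)),
       maf = 0.1, prevalence = 0.026),
  list(or = or_grid(c(1.15, 0.40, 0.17, 0.28, 4.23, 4.89, 1.15, 0.06, 5.56)),
       maf = 0.1, prevalence = 0.017),
  list(or = or_grid(c(0.84, 1.35, 0.80, 1.30, 0.39, 1.45, 1.45, 0.13, 1.04)),
       maf = 0.2, prevalence = 0.052),
  list(or = or_grid(c(0.52, 1.07, 1.89, 1.30, 0.92, 0.59, 1.21, 1.08, 0.33)),
       maf = 0.4, prevalence = 0.048)
)

hwe_freq <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Resolve an odds-ratio grid into a two-locus penetrance model
#'
#' Each genotype cell's odds of disease is its odds ratio times a common
#' baseline odds `b`: `penetrance_ij = OR_ij * b / (1 + OR_ij * b)`. The
#' baseline is solved (by root bisection over `(1e-8, 1e3)`) so that the
#' Hardy-Weinberg-weighted mean penetrance equals the target population
#' prevalence. A structural OR of 0 forces penetrance exactly 0.
#'
#' @param or_table 3x3 matrix of genotype odds ratios (rows: second-locus
#'   genotypes BB/Bb/bb; columns: first-locus genotypes AA/Aa/aa); entries
#'   must be positive, or exactly 0 for a structural zero.
#' @param maf minor allele frequency shared by both causal loci, in
#'   (0, 0.5).
#' @param prevalence target population disease probability, in (0, 1).
#' @return An object of class `penetrance_model`: list with `or_table`,
#'   `maf`, `prevalence`, `baseline_odds` and the derived 3x3 `penetrance`
#'   matrix.
#' @examples
#' m <- penetrance_model(1)            # built-in model 1
#' sum(outer(hwe_genotype_freq(m$maf), hwe_genotype_freq(m$maf)) * m$penetrance)
#' @export
derive_penetrance <- function(or_table, maf, prevalence) {
  or_table <- as.matrix(or_table)
  stopifnot(identical(dim(or_table), c(3L, 3L)))
  if (any(or_table < 0) || anyNA(or_table))
    stop("odds ratios must be positive (or exactly 0 for a structural zero)")
  if (maf <= 0 || maf >= 0.5) stop("maf must be in (0, 0.5)")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  w <- outer(hwe_freq(maf), hwe_freq(maf))  # rows locus B, cols locus A
  pen_at <- function(b) or_table * b / (1 + or_table * b)  # OR 0 -> 0
  f <- function(b) sum(w * pen_at(b)) - prevalence
  lo <- 1e-8; hi <- 1e3
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible model: no baseline odds in (1e-8, 1e3) attains prevalence ",
         prevalence)
  b <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  if (abs(f(b)) > 1e-10)
    stop("baseline-odds solve did not converge (residual ", signif(f(b), 3), ")")
  pen <- pen_at(b)
  dimnames(pen) <- dimnames(or_table)
  structure(list(or_table = or_table, maf = maf, prevalence = prevalence,
                 baseline_odds = b, penetrance = pen),
            class = "penetrance_model")
}

#' @rdname derive_penetrance
#' @param model built-in model number 1-8.
#' @export
penetrance_model <- function(model) {
  model <- as.integer(model)
  if (model < 1L || model > length(two_locus_models))
    stop("model must be between 1 and ", length(two_locus_models))
  m <- two_locus_models[[model]]
  out <- derive_penetrance(m$or, m$maf, m$prevalence)
  out$model_id <- model
  out
}

#' @rdname derive_penetrance
#' @param q minor allele frequency.
#' @export
hwe_genotype_freq <- function(q) {
  if (any(q <= 0 | q >= 1)) stop("allele frequency must be in (0, 1)")
  hwe_freq(q)
}

#' @export
print.penetrance_model <- function(x, ...) {
  if (!is.null(x$model_id)) cat("Two-locus penetrance model ", x$model_id, "\n", sep = "")
  else cat("Two-locus penetrance model\n")
  cat(sprintf("  MAF = %g, prevalence = %g, baseline odds = %.6g\n",
              x$maf, x$prevalence, x$baseline_odds))
  cat("  penetrance:\n")
  print(round(x$penetrance, 5))
  invisible(x)
}

#' Draw causal-pair genotypes conditional on disease status
#'
#' Retrospective sampling: under Hardy-Weinberg equilibrium and the
#' model's penetrance table, a case's two-locus genotype `(i, j)` has
#' probability proportional to `hwe_i * hwe_j * penetrance_ij`, a
#' control's to `hwe_i * hwe_j * (1 - penetrance_ij)`.
#'
#' @param model a [penetrance_model].
#' @param status `"case"` or `"control"`.
#' @param n number of individuals to draw.
#' @return `n x 2` integer matrix of genotype codes (columns: locus A,
#'   locus B).
#' @export
sample_causal_pair <- function(model, status = c("case", "control"), n) {
  stopifnot(inherits(model, "penetrance_model"))
  status <- match.arg(status)
  w <- outer(hwe_freq(model$maf), hwe_freq(model$maf))
  lik <- if (status == "case") model$penetrance else 1 - model$penetrance
  prob <- as.numeric(w * lik)   # column-major: cell (i, j) at i + 3*(j-1)
  cell <- sample.int(9L, n, replace = TRUE, prob = prob)
  i <- (cell - 1L) %% 3L        # locus B genotype code
  j <- (cell - 1L) %/% 3L       # locus A genotype code
  cbind(A = j, B = i)
}

#' Map a simulation design group to its dimensions
#'
#' Fifteen design groups cross five SNP-panel sizes (10, 50, 100, 500,
#' 1000) with three balanced sample sizes (400, 1000, 2000): groups 1-3
#' are 10 SNPs with 400/1000/2000 samples, groups 4-6 are 50 SNPs, and so
#' on.
#'
#' @param group design group number 1-15.
#' @return list with `group`, `n_snp` and `n_sample`.
#' @export
simulation_design <- function(group) {
  group <- as.integer(group)
  if (group < 1L || group > 15L) stop("group must be between 1 and 15")
  n_snp <- c(10L, 50L, 100L, 500L, 1000L)[(group - 1L) %/% 3L + 1L]
  n_sample <- c(400L, 1000L, 2000L)[(group - 1L) %% 3L + 1L]
  list(group = group, n_snp = n_snp, n_sample = n_sample)
}

#' Simulate a balanced case-control SNP dataset
#'
#' Generates `n_sample / 2` cases and `n_sample / 2` controls over
#' `n_snp` SNPs. When a two-locus `model` is given, the SNPs at the
#' `causal` positions are drawn retrospectively from the model
#' ([sample_causal_pair()]); all remaining SNPs are phenotype-independent
#' Hardy-Weinberg noise with per-SNP minor allele frequencies drawn
#' uniformly from `maf_noise` (or fixed, if `maf_noise` is a scalar).
#' With `model = NULL` every SNP is noise -- the global-null generator.
#'
#' @param n_snp number of SNPs (>= 2 when a causal model is embedded).
#' @param n_sample total sample size (even; split 1:1 case:control).
#' @param model a [penetrance_model], a built-in model number 1-8, or
#'   `NULL` for a global-null dataset.
#' @param group alternatively, a design group 1-15 setting `n_snp` and
#'   `n_sample` (overrides both).
#' @param maf_noise range (length 2) or fixed value of noise-SNP minor
#'   allele frequencies; default `c(0.05, 0.5)`.
#' @param causal positions of the two causal SNPs (default 1 and 2).
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return a [genotype_data] object; cases first, then controls.
#' @examples
#' d <- simulate_case_control(n_snp = 10, n_sample = 400, model = 1, seed = 1)
#' d
#' @export
simulate_case_control <- function(n_snp = 10L, n_sample = 400L, model = NULL,
                                  group = NULL, maf_noise = c(0.05, 0.5),
                                  causal = c(1L, 2L), seed = NULL) {
  if (!is.null(group)) {
    des <- simulation_design(group)
    n_snp <- des$n_snp
    n_sample <- des$n_sample
  }
  n_snp <- as.integer(n_snp); n_sample <- as.integer(n_sample)
  if (n_sample %% 2L != 0L) stop("n_sample must be even (balanced 1:1 design)")
  if (is.numeric(model) && length(model) == 1L) model <- penetrance_model(model)
  if (!is.null(model) && !inherits(model, "penetrance_model"))
    stop("model must be NULL, a model number, or a penetrance_model")
  if (!is.null(model)) {
    causal <- as.integer(causal)
    if (length(causal) != 2L || anyDuplicated(causal) ||
        any(causal < 1L | causal > n_snp))
      stop("causal must be two distinct SNP positions within 1..n_snp")
  }
  n_case <- n_sample %/% 2L
  with_seed(seed, {
    G <- matrix(NA_integer_, n_sample, n_snp)
    noise_cols <- if (is.null(model)) seq_len(n_snp) else setdiff(seq_len(n_snp), causal)
    mafs <- rep(NA_real_, n_snp)
    if (length(noise_cols)) {
      mafs[noise_cols] <- if (length(maf_noise) == 2L)
        stats::runif(length(noise_cols), maf_noise[1], maf_noise[2])
      else rep(maf_noise, length(noise_cols))
      for (j in noise_cols)
        G[, j] <- stats::rbinom(n_sample, 2L, mafs[j])
    }
    if (!is.null(model)) {
      G[seq_len(n_case), causal] <- sample_causal_pair(model, "case", n_case)
      G[n_case + seq_len(n_sample - n_case), causal] <-
        sample_causal_pair(model, "control", n_sample - n_case)
      mafs[causal] <- model$maf
    }
    out <- genotype_data(G, phenotype = rep(c(1L, 0L), c(n_case, n_sample - n_case)))
    attr(out, "maf") <- mafs
    attr(out, "causal") <- if (is.null(model)) NULL else causal
    attr(out, "model_id") <- model$model_id
    out
  })
}

#' Hit-ratio power experiment
#'
#' Runs the empirical power protocol: for each (model, group) cell,
#' simulate `n_replicates` datasets with the causal pair embedded at
#' positions 1 and 2, analyse each with the requested methods, and record
#' the fraction of replicates in which the true pair ranks first among all
#' two-locus combinations (the "hit ratio"). Methods:
#' \describe{
#'   \item{`U_r`}{rank by standardized relative information gain. Since
#'     standardization is monotone, the rank -- hence the hit ratio -- is
#'     identical to the raw-R0 rank, so no permutations are spent here.}
#'   \item{`MDR_BA`}{multifactor dimensionality reduction, best pair by
#'     mean testing balanced accuracy over the cross-validation folds.}
#'   \item{`MDR_CVC`}{MDR, best pair by cross-validation consistency (ties
#'     by mean testing balanced accuracy).}
#' }
#'
#' @param models vector of built-in model numbers (1-8).
#' @param groups vector of design groups (1-15).
#' @param n_replicates replicated datasets per (model, group) cell
#'   (default 100).
#' @param methods subset of `c("U_r", "MDR_BA", "MDR_CVC")`.
#' @param seed master seed; replicate r of each cell uses a seed derived
#'   deterministically from it, so any cell is reproducible in isolation.
#' @param mdr_folds cross-validation folds for the MDR methods.
#' @param max_combinations per-scan safety limit.
#' @return data frame with one row per (model, group, method): `model`,
#'   `group`, `n_snp`, `n_sample`, `method`, `hits`, `n_replicates`,
#'   `hit_ratio`.
#' @export
power_experiment <- function(models, groups, n_replicates = 100L,
                             methods = c("U_r", "MDR_BA", "MDR_CVC"),
                             seed = NULL, mdr_folds = 10L,
                             max_combinations = 1e6) {
  methods <- match.arg(methods, several.ok = TRUE)
  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else as.integer(seed)
  grid <- expand.grid(model = models, group = groups)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    model <- grid$model[g]; group <- grid$group[g]
    des <- simulation_design(group)
    if (choose(des$n_snp, 2) > max_combinations)
      stop("group ", group, " needs ", choose(des$n_snp, 2),
           " pairwise scans per replicate, above max_combinations")
    hits <- stats::setNames(integer(length(methods)), methods)
    for (r in seq_len(n_replicates)) {
      rseed <- (base_seed + 7919L * (g - 1L) + r) %% .Machine$integer.max
      d <- simulate_case_control(group = group, model = model, seed = rseed)
      causal <- sort(attr(d, "causal"))
      if (any(c("U_r", "MDR_BA", "MDR_CVC") %in% methods)) {
        if ("U_r" %in% methods) {
          scan <- scan_rig(d, order = 2L, top_n = 1L,
                           max_combinations = max_combinations)
          top <- sort(attr(scan, "indices")[, 1L])
          hits["U_r"] <- hits["U_r"] + all(top == causal)
        }
        if (any(c("MDR_BA", "MDR_CVC") %in% methods)) {
          mdr <- mdr_cv(d, order = 2L, folds = mdr_folds, seed = rseed + 1L,
                        max_combinations = max_combinations)
          if ("MDR_BA" %in% methods) {
            top <- sort(mdr_top_pair(mdr, "BA"))
            hits["MDR_BA"] <- hits["MDR_BA"] + all(top == causal)
          }
          if ("MDR_CVC" %in% methods) {
            top <- sort(mdr_top_pair(mdr, "CVC"))
            hits["MDR_CVC"] <- hits["MDR_CVC"] + all(top == causal)
          }
        }
      }
    }
    out[[g]] <- data.frame(model = model, group = group,
                           n_snp = des$n_snp, n_sample = des$n_sample,
                           method = methods, hits = as.integer(hits),
                           n_replicates = as.integer(n_replicates),
                           hit_ratio = as.numeric(hits) / n_replicates,
                           row.names = NULL)
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- base_seed
  res
}
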