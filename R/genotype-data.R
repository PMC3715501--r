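#' Case-control genotype dataset
#'
#' Container for a samples-by-SNPs genotype matrix with a binary disease
#' phenotype. Genotypes are coded as minor-allele counts: 0 (homozygous
#' major, AA), 1 (heterozygous, Aa), 2 (homozygous minor, aa). Missing
#' genotypes are `NA` and are handled by per-combination complete-case
#' exclusion in all downstream analyses.
#'
#' @param genotypes numeric or integer matrix, `n_samples x n_snps`, values
#'   in \{0, 1, 2\} or `NA`.
#' @param phenotype binary vector of length `n_samples`; 1 = case,
#'   0 = control.
#' @param snp_ids optional character vector of unique SNP labels; defaults
#'   to the matrix column names or `SNP1..SNPp`.
#' @param sample_ids optional character vector of unique sample labels;
#'   defaults to row names or `S1..Sn`.
#'
#' @return An object of class `genotype_data`: a list with elements
#'   `genotypes` (integer matrix), `phenotype` (integer vector), `snp_ids`
#'   and `sample_ids`.
#' @examples
#' g <- matrix(sample(0:2, 40, replace = TRUE), nrow = 10)
#' d <- genotype_data(g, phenotype = rep(0:1, each = 5))
#' d
#' @export
genotype_data <- function(genotypes, phenotype, snp_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code at row ", idx[1L], ", column ", idx[2L],
         ": genotypes must be 0, 1, 2 or NA")
  }
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length (", length(phenotype),
         ") does not match the number of samples (", nrow(genotypes), ")")
  if (anyNA(phenotype) || !all(phenotype %in% 0:1))
    stop("phenotype must be coded 0 (control) / 1 (case) with no missing values")
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(genotypes)) stop("snp_ids length mismatch")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ", paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(genotypes)) stop("sample_ids length mismatch")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(genotypes) <- NULL
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_ids = snp_ids, sample_ids = sample_ids),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("Case-control genotype dataset\n")
  cat("  samples: ", length(x$sample_ids),
      " (", sum(x$phenotype == 1L), " cases / ",
      sum(x$phenotype == 0L), " controls)\n", sep = "")
  cat("  SNPs:    ", length(x$snp_ids), "\n", sep = "")
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss > 0L)
    cat("  missing genotypes: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$genotypes)

# both phenotype classes must be present before any entropy statistic is
# defined (H(Y) > 0)
check_two_classes <- function(data) {
  if (length(unique(data$phenotype)) < 2L)
    stop("analysis requires both cases and controls in the dataset")
  invisible(TRUE)
}

#' Permute the phenotype labels of a dataset
#'
#' Returns a copy of the dataset whose phenotype vector is a uniform random
#' permutation (without replacement) of the original. Genotypes and all ids
#' are untouched, so case/control totals are preserved exactly -- the label
#' shuffle used to build the permutation null.
#'
#' @param data a [genotype_data] object.
#' @return a [genotype_data] object with shuffled phenotype.
#' @export
permute_phenotype <- function(data) {
  stopifnot(inherits(data, "genotype_data"))
  data$phenotype <- sample(data$phenotype)
  data
}

# Set the RNG seed locally if supplied, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
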