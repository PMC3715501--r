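#' Read a case-control genotype table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`tsv` / `csv`}{one header row; a `phenotype` column coded 0/1;
#'     an optional `sample_id` column; every other column a SNP with
#'     genotype codes 0/1/2 or NA.}
#'   \item{`plink_raw`}{the PLINK `--recode A` dialect: columns FID IID
#'     PAT MAT SEX PHENOTYPE followed by additive-dosage SNP columns.
#'     PHENOTYPE 1/2 is mapped to control/case (0/1); samples with
#'     PHENOTYPE 0, -9 or NA are dropped with a logged count.}
#' }
#'
#' @param path file path.
#' @param dialect `"tsv"` (default), `"csv"` or `"plink_raw"`.
#' @return a [genotype_data] object.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink_raw") return(read_plink_raw(path))
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"phenotype" %in% names(df))
    stop("no 'phenotype' column in ", path)
  sample_ids <- NULL
  if ("sample_id" %in% names(df)) {
    sample_ids <- as.character(df$sample_id)
    df$sample_id <- NULL
  }
  pheno <- df$phenotype
  df$phenotype <- NULL
  if (!all(pheno %in% 0:1))
    stop("phenotype column must be coded 0/1 (row ",
         which(!pheno %in% 0:1)[1L], ")")
  snp_ids <- names(df)
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids in header: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  G <- as.matrix(df)
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code '", G[w[1L], w[2L]], "' at row ", w[1L],
         ", column '", snp_ids[w[2L]], "'")
  }
  genotype_data(G, phenotype = pheno, snp_ids = snp_ids, sample_ids = sample_ids)
}

read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(fixed %in% names(df)[seq_len(6L)]))
    stop("not a PLINK .raw file: expected header columns ",
         paste(fixed, collapse = " "))
  pheno_raw <- df$PHENOTYPE
  keep <- !is.na(pheno_raw) & pheno_raw %in% c(1, 2)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("dropped ", dropped, " sample(s) with missing phenotype (0/-9/NA)")
  if (!any(keep)) stop("no samples with a usable PHENOTYPE in ", path)
  df <- df[keep, , drop = FALSE]
  snp_cols <- setdiff(names(df), fixed)
  if (!length(snp_cols)) stop("no SNP dosage columns in ", path)
  if (anyDuplicated(snp_cols))
    stop("duplicate SNP ids in header: ",
         paste(unique(snp_cols[duplicated(snp_cols)]), collapse = ", "))
  G <- as.matrix(df[, snp_cols, drop = FALSE])
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid dosage '", G[w[1L], w[2L]], "' at sample ", df$IID[w[1L]],
         ", column '", snp_cols[w[2L]], "'")
  }
  genotype_data(G, phenotype = as.integer(df$PHENOTYPE == 2),
                snp_ids = snp_cols,
                sample_ids = make.unique(as.character(df$IID)))
}

#' Write a genotype dataset as delimited text
#'
#' Writes the package's genotype table dialect: columns `sample_id`,
#' `phenotype`, then one column per SNP. [read_genotypes()] on the result
#' reproduces the dataset exactly.
#'
#' @param data a [genotype_data] object.
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(data, path, dialect = c("tsv", "csv")) {
  stopifnot(inherits(data, "genotype_data"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(sample_id = data$sample_ids, phenotype = data$phenotype,
                   stringsAsFactors = FALSE)
  G <- as.data.frame(data$genotypes)
  names(G) <- data$snp_ids
  utils::write.table(cbind(df, G), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serializable run report for a fitted scan
#'
#' Collects everything needed to reproduce or re-plot a [rig_scan()] run:
#' the input digest, the ranked combinations with R0 / U_r / adjusted
#' p-values, the null summary, the cutoff, seeds, package version and a
#' timestamp. The report round-trips through JSON.
#'
#' @param fit a [rig_scan] object.
#' @param path optional JSON output path.
#' @param top_n number of top combinations embedded in the report.
#' @return the report list, invisibly if written to `path`.
#' @export
run_report <- function(fit, path = NULL, top_n = 100L) {
  stopifnot(inherits(fit, "rig_scan"))
  res <- utils::head(fit$results, top_n)
  report <- list(
    tool = "rigscan",
    version = as.character(utils::packageVersion("rigscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = fit$data_digest,
    order = fit$order,
    seed = fit$seed,
    null = list(n_perm = fit$null$n_perm, mu = fit$null$mu,
                sigma = fit$null$sigma,
                quantiles = as.list(stats::quantile(fit$null$M, c(0.5, 0.95, 0.99)))),
    cutoff = fit$cutoff,
    n_significant = fit$n_significant,
    results = res
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}

#' @rdname run_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
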