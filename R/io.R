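#' Write a cohort to delimited files
#'
#' Emits three tab-delimited files under `dir`: `<prefix>_phenotypes.tsv`
#' (sample id, y1, y2, any covariates), `<prefix>_dosages1.tsv` and
#' `<prefix>_dosages2.tsv` (sample id plus one column per instrument, header
#' row carrying the SNP identifiers). The latent confounder, when present, is
#' written into the phenotype file as a `confounder` column so simulated
#' cohorts round-trip exactly.
#'
#' @param data A `bimr_data` cohort.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"cohort"`).
#' @return Invisibly, the three file paths (named `phenotypes`, `dosages1`,
#'   `dosages2`).
#' @export
write_cohort <- function(data, dir, prefix = "cohort") {
  stopifnot(inherits(data, "bimr_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(data$y1)
  ids <- sprintf("S%05d", seq_len(n))
  ph <- data.frame(sample_id = ids, y1 = data$y1, y2 = data$y2)
  if (!is.null(data$covariates)) {
    cv <- as.data.frame(data$covariates)
    if (is.null(colnames(data$covariates)))
      names(cv) <- sprintf("cov%d", seq_along(cv))
    ph <- cbind(ph, cv)
  }
  if (!is.null(data$confounder)) ph$confounder <- data$confounder
  snp_names <- function(X, tag) {
    if (!is.null(colnames(X))) colnames(X) else sprintf("snp%s_%d", tag, seq_len(ncol(X)))
  }
  d1 <- data.frame(sample_id = ids, data$X1)
  names(d1)[-1] <- snp_names(data$X1, "1")
  d2 <- data.frame(sample_id = ids, data$X2)
  names(d2)[-1] <- snp_names(data$X2, "2")
  paths <- c(phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv")),
             dosages1 = file.path(dir, paste0(prefix, "_dosages1.tsv")),
             dosages2 = file.path(dir, paste0(prefix, "_dosages2.tsv")))
  utils::write.table(ph, paths["phenotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d1, paths["dosages1"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(d2, paths["dosages2"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from delimited files
#'
#' Inverse of [write_cohort()]. All files must carry a `sample_id` first
#' column; rows are aligned by identifier (the file order need not agree) and
#' unmatched identifiers are an error. An instrument identifier appearing in
#' both dosage files is rejected, since one SNP cannot satisfy the exclusion
#' restriction for both traits at once.
#'
#' @param phenotype_file Path to the phenotype/covariate table (must contain
#'   `y1` and `y2` columns).
#' @param dosage1_file,dosage2_file Paths to the trait-1 and trait-2
#'   instrument dosage tables.
#' @param covariate_cols Optional character vector naming phenotype-file
#'   columns to load as observed covariates.
#' @return A validated `bimr_data` cohort.
#' @export
read_cohort <- function(phenotype_file, dosage1_file, dosage2_file,
                        covariate_cols = NULL) {
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    utils::read.table(p, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  ph <- read1(phenotype_file); d1 <- read1(dosage1_file); d2 <- read1(dosage2_file)
  for (d in list(ph, d1, d2))
    if (!"sample_id" %in% names(d)) stop("every file needs a sample_id column")
  if (!all(c("y1", "y2") %in% names(ph)))
    stop("phenotype file must contain y1 and y2 columns")
  align <- function(d, label) {
    missing_ids <- setdiff(ph$sample_id, d$sample_id)
    extra_ids <- setdiff(d$sample_id, ph$sample_id)
    if (length(missing_ids) || length(extra_ids))
      stop("sample mismatch in ", label, ": ",
           paste(utils::head(c(missing_ids, extra_ids), 5L), collapse = ", "))
    d[match(ph$sample_id, d$sample_id), , drop = FALSE]
  }
  d1 <- align(d1, "dosage file 1"); d2 <- align(d2, "dosage file 2")
  shared <- intersect(names(d1)[-1], names(d2)[-1])
  if (length(shared))
    stop("instrument(s) assigned to both traits: ",
         paste(shared, collapse = ", "))
  covariates <- NULL
  if (!is.null(covariate_cols)) {
    absent <- setdiff(covariate_cols, names(ph))
    if (length(absent)) stop("covariate column(s) not found: ",
                             paste(absent, collapse = ", "))
    covariates <- as.matrix(ph[covariate_cols])
  }
  X1 <- as.matrix(d1[-1]); X2 <- as.matrix(d2[-1])
  bimr_dataset(ph$y1, ph$y2, X1, X2, covariates = covariates,
               confounder = if ("confounder" %in% names(ph)) ph$confounder else NULL)
}

#' Extract a dosage matrix from a VCF file
#'
#' Builds an n x k dosage matrix for the requested variants from either the
#' `DS` dosage field (kept as-is, possibly fractional) or by counting
#' alternate alleles in `GT`. Missing genotypes are an error by default or
#' replaced by the variant's mean dosage with `missing = "impute"`.
#'
#' @param vcf_path Path to a VCF (plain or bgzipped).
#' @param variant_ids Character vector of variant IDs to extract, in order.
#' @param field `"GT"` (allele counting, default) or `"DS"`.
#' @param missing `"error"` or `"impute"`.
#' @return A numeric n x k matrix, columns named by variant ID.
#' @export
read_vcf_dosages <- function(vcf_path, variant_ids, field = c("GT", "DS"),
                             missing = c("error", "impute")) {
  field <- match.arg(field); missing <- match.arg(missing)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ids <- vcfR::getID(vcf)
  idx <- match(variant_ids, ids)
  if (anyNA(idx))
    stop("variant id(s) absent from VCF: ",
         paste(variant_ids[is.na(idx)], collapse = ", "))
  raw <- vcfR::extract.gt(vcf, element = field)[idx, , drop = FALSE]
  dos <- if (field == "DS") {
    apply(raw, c(1, 2), function(x) suppressWarnings(as.numeric(x)))
  } else {
    # count ALT alleles from genotype strings like 0/1, 1|1, ./.
    apply(raw, c(1, 2), function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dos <- t(dos)  # samples x variants
  colnames(dos) <- variant_ids
  if (anyNA(dos)) {
    if (missing == "error") {
      bad <- colnames(dos)[colSums(is.na(dos)) > 0]
      stop("missing genotypes at: ", paste(bad, collapse = ", "))
    }
    for (j in seq_len(ncol(dos))) {
      na <- is.na(dos[, j])
      if (any(na)) dos[na, j] <- mean(dos[!na, j])
    }
  }
  dos
}
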