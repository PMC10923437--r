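#' One-sample two-trait cohort with per-trait instrument sets
#'
#' Bundles the two continuous phenotypes with the dosage matrix of each
#' trait's instrument set, optional observed covariates, and (for simulated
#' cohorts) the latent confounder, which is retained for diagnostics only and
#' never used by the estimators unless explicitly requested.
#'
#' @param y1,y2 Numeric phenotype vectors of length n.
#' @param X1 n x k1 dosage matrix of trait-1 instruments. Simulated dosages
#'   are integers in `{0, 1, 2}`; real data may carry fractional dosages in
#'   `[0, 2]`.
#' @param X2 n x k2 dosage matrix of trait-2 instruments.
#' @param covariates Optional n x p matrix of observed covariates.
#' @param confounder Optional length-n vector of the latent confounder.
#' @return A validated object of class `bimr_data`.
#' @seealso [validate_dataset()]
#' @export
bimr_dataset <- function(y1, y2, X1, X2, covariates = NULL, confounder = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  validate_dataset(structure(list(
    y1 = as.numeric(y1), y2 = as.numeric(y2),
    X1 = X1, X2 = X2,
    covariates = covariates, confounder = confounder
  ), class = "bimr_data"))
}

#' Validate a cohort object
#'
#' Checks that every component has the same number of rows, that no missing
#' values remain, and that dosages lie in `[0, 2]`. Rows carrying missing
#' values are reported by index rather than silently dropped, so the caller
#' decides how to handle them.
#'
#' @param data A `bimr_data` object (or a bare list with the same fields).
#' @return The validated `bimr_data` object, invisibly unchanged.
#' @export
validate_dataset <- function(data) {
  need <- c("y1", "y2", "X1", "X2")
  if (!all(need %in% names(data)))
    stop("dataset must contain y1, y2, X1, X2")
  n <- length(data$y1)
  lens <- c(y2 = length(data$y2), X1 = nrow(data$X1), X2 = nrow(data$X2))
  if (!is.null(data$covariates)) lens <- c(lens, covariates = nrow(data$covariates))
  if (!is.null(data$confounder)) lens <- c(lens, confounder = length(data$confounder))
  bad <- lens != n
  if (any(bad))
    stop("dimension mismatch: y1 has ", n, " rows but ",
         paste(sprintf("%s has %d", names(lens)[bad], lens[bad]), collapse = ", "))
  if (ncol(data$X1) < 1L || ncol(data$X2) < 1L)
    stop("each instrument set must contain at least one SNP")
  miss <- !stats::complete.cases(data$y1, data$y2, data$X1, data$X2,
                                 data$covariates)
  if (any(miss))
    stop("missing values in rows: ",
         paste(utils::head(which(miss), 10L), collapse = ", "),
         if (sum(miss) > 10L) sprintf(" (and %d more)", sum(miss) - 10L) else "")
  rng <- range(data$X1, data$X2)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; observed range ",
         paste(format(rng), collapse = " .. "))
  if (!inherits(data, "bimr_data")) class(data) <- "bimr_data"
  data
}

#' @export
print.bimr_data <- function(x, ...) {
  cat(sprintf("Two-trait MR cohort: n = %d, %d trait-1 instruments, %d trait-2 instruments\n",
              length(x$y1), ncol(x$X1), ncol(x$X2)))
  if (!is.null(x$covariates))
    cat(sprintf("  %d observed covariate(s)\n", ncol(x$covariates)))
  if (!is.null(x$confounder))
    cat("  latent confounder retained for diagnostics\n")
  invisible(x)
}

# Exchange the roles of the two traits (and their instrument sets).
# Every bidirectional estimator is equivariant under this relabelling.
#' Swap the two traits of a cohort
#'
#' Returns the same cohort with trait 1 and trait 2 (and their instrument
#' sets) exchanged. Useful for symmetry checks: every bidirectional estimator
#' must return the two directed estimates exchanged on the swapped cohort.
#' @param data A `bimr_data` object.
#' @return A `bimr_data` object with roles exchanged.
#' @export
swap_traits <- function(data) {
  stopifnot(inherits(data, "bimr_data"))
  structure(list(y1 = data$y2, y2 = data$y1, X1 = data$X2, X2 = data$X1,
                 covariates = data$covariates, confounder = data$confounder),
            class = "bimr_data")
}
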