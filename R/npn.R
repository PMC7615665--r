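# Nonparanormal transformation and covariate residualization.

#' Shrunken-ECDF nonparanormal transform of one column
#'
#' Maps ranks through the shrunken empirical CDF `u_i = rank_i / (n + 1)`
#' (average ranks for ties), applies the standard-normal quantile function,
#' mean-centres, and rescales to unit sample SD. Rank-based, hence invariant
#' to any strictly increasing transform of the input; for large Gaussian
#' samples it approaches the identity map.
#'
#' @param column numeric vector, length >= 2, no missing values.
#' @return transformed numeric vector with mean 0 and sample SD 1.
#' @export
npn_shrunken <- function(column) {
  if (anyNA(column)) stop("npn_shrunken requires complete data; impute first")
  n <- length(column)
  if (n < 2L) stop("npn_shrunken needs at least 2 observations")
  if (length(unique(column)) == 1L)
    stop("constant column: ranks are degenerate, cannot transform")
  z <- stats::qnorm(rank(column, ties.method = "average") / (n + 1))
  z <- z - mean(z)
  z / stats::sd(z)
}

#' Nonparanormal transform of a complete data matrix, column-wise
#' @param x complete numeric matrix.
#' @return matrix of the same shape; every column mean 0, sample SD 1.
#' @export
npn_transform <- function(x) {
  out <- apply(x, 2L, npn_shrunken)
  dimnames(out) <- dimnames(x)
  out
}

#' Residualize score columns on age and sex
#'
#' Sensitivity-analysis adjustment: each column is replaced by the residuals
#' of an ordinary least-squares fit on sex and the block-matched collection
#' age, then re-standardised to mean 0 / unit SD. Rows with a missing
#' covariate are dropped (with attribute `kept_rows` recording the retained
#' index).
#'
#' @param dataset complete individuals x 13 matrix (one imputed dataset).
#' @param covariates data.frame with `sex`, `age_trait`, `age_stressor`,
#'   `age_depression`.
#' @param schema variable schema (block-matches the age columns).
#' @return residualised matrix with attribute `kept_rows`.
#' @export
residualize <- function(dataset, covariates, schema) {
  stopifnot(nrow(dataset) == nrow(covariates))
  block_of <- c(trait = "age_trait", stressor_dysregulation = "age_stressor",
                depression = "age_depression")
  keep <- stats::complete.cases(covariates[, c("sex", unname(block_of))])
  if (sum(keep) < 10L) stop("too few rows with complete covariates to residualize")
  out <- matrix(NA_real_, sum(keep), ncol(dataset),
                dimnames = list(NULL, colnames(dataset)))
  for (k in seq_len(ncol(dataset))) {
    age <- covariates[keep, block_of[[schema$block[k]]]]
    X <- cbind(1, covariates$sex[keep], age)
    if (qr(X)$rank < ncol(X))
      stop("collinear covariates: cannot residualize on age and sex")
    fit <- stats::lm.fit(X, dataset[keep, k])
    r <- fit$residuals
    if (stats::sd(r) < 1e-12)
      stop(sprintf("column '%s' is an exact linear function of the covariates",
                   colnames(dataset)[k]))
    out[, k] <- (r - mean(r)) / stats::sd(r)
  }
  attr(out, "kept_rows") <- which(keep)
  out
}
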