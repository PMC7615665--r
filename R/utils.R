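# internal helpers shared across modules

#' Derive a reproducible substream seed
#'
#' A single global integer seed fans out to independent per-stage substreams so
#' that pipeline stages can be rerun in isolation without disturbing each other.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @param index integer substream index within the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage_id <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # affine hash in double precision; all terms < 2^53
  as.integer((abs(seed) * 48271 + stage_id * 10007 + index * 65537) %% 2147483647)
}

# symmetric positive-definite check with an eigenvalue floor
is_spd <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < 1e-8 &&
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol
}

# inverse via Cholesky; errors carry the caller's context
chol_inv <- function(m) chol2inv(chol(m))

`%||%` <- function(a, b) if (is.null(a)) b else a

vlapply <- function(x, f, ...) vapply(x, f, logical(1L), ...)
vnapply <- function(x, f, ...) vapply(x, f, numeric(1L), ...)
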