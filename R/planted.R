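# Planted ground-truth networks for the synthetic cohorts.

#' Default planted partial-correlation network
#'
#' Builds the population network the synthetic cohorts are drawn from. The
#' `"paper_like"` scenario mirrors the qualitative structure recovered in the
#' two-cohort study this pipeline reimplements: neurodevelopmental traits are
#' interconnected (11 of 21 pairs), traits connect to the stressor /
#' dysregulation block (6 of 21), the stressor / dysregulation block connects
#' to depressive symptoms, the depression waves form a chain, and there are
#' exactly zero direct trait-depression edges -- so any trait-depression
#' dependence in the data is purely indirect. Symptom scales are coded
#' higher-is-worse and ability scales higher-is-better, which fixes the edge
#' signs. `"dense"` plants a uniform weak partial correlation on every pair;
#' `"null"` plants the empty network.
#'
#' Numeric magnitudes are calibration choices of the generator, not estimates.
#'
#' @param scenario one of `"paper_like"`, `"dense"`, `"null"`.
#' @return an object of class `planted_network`: list with `precision`
#'   (13 x 13, unit diagonal), `partials` (implied partial correlations) and
#'   `labels`.
#' @export
default_planted_network <- function(scenario = c("paper_like", "dense", "null")) {
  scenario <- tryCatch(match.arg(scenario), error = function(e)
    stop("unknown scenario '", scenario[1],
         "'; valid scenarios: paper_like, dense, null", call. = FALSE))
  vars <- ndnet_variables()
  rho <- matrix(0, 13, 13, dimnames = list(vars, vars))
  if (scenario == "paper_like") {
    e <- function(i, j, v) rho[i, j] <<- rho[j, i] <<- v
    # trait--trait (11 of 21 nonzero; autistic _|_ general_cognitive, learning)
    e(1, 2, 0.25); e(1, 3, 0.20); e(2, 3, 0.45)
    e(1, 5, -0.20); e(1, 6, -0.25); e(2, 6, -0.10)
    e(3, 4, -0.15); e(3, 7, -0.15)
    e(4, 5, 0.15); e(4, 7, 0.40); e(5, 6, 0.35)
    # trait--stressor/dysregulation (6 of 21 nonzero)
    e(2, 8, 0.30); e(1, 9, 0.25); e(4, 10, 0.35)
    e(7, 10, 0.30); e(3, 10, -0.15); e(6, 9, -0.15)
    # within stressor/dysregulation block
    e(8, 9, 0.20); e(9, 10, -0.10)
    # stressor/dysregulation--depression (the only path into depression)
    e(8, 11, 0.20); e(9, 11, 0.18); e(10, 12, -0.12)
    # depression wave chain
    e(11, 12, 0.35); e(12, 13, 0.30); e(11, 13, 0.10)
  } else if (scenario == "dense") {
    rho[] <- 0.07
    diag(rho) <- 0
  }
  theta <- diag(13) - rho
  dimnames(theta) <- dimnames(rho)
  if (!is_spd(theta))
    stop("planted precision matrix is not positive definite")
  diag(rho) <- 1
  structure(list(precision = theta, partials = rho, labels = vars),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  nz <- sum(x$partials[upper.tri(x$partials)] != 0)
  cat("<planted_network> 13 nodes,", nz, "nonzero edges of 78\n")
  invisible(x)
}

#' Partial correlations implied by a precision matrix
#'
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)` off the diagonal, 1 on it.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @return partial-correlation matrix of the same dimension.
#' @export
partial_from_precision <- function(theta) {
  if (!is_spd(theta)) stop("precision matrix must be symmetric positive definite")
  d <- sqrt(diag(theta))
  rho <- -theta / tcrossprod(d)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(theta)
  rho
}
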