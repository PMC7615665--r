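# Bayesian estimation of the Gaussian graphical model.
#
# Two-block Gibbs sampler over the precision matrix Theta under the
# calibrated matrix-F prior (see prior.R): both full conditionals are
# Wishart, so each iteration is two Wishart draws and two Cholesky inverses.
#     Theta | Phi, data ~ W(n + nu1, (S + Phi)^-1)
#     Phi   | Theta     ~ W(nu1 + nu2, (Theta + (bI)^-1)^-1)
# with S = X'X of the standardized (nonparanormal) data.

new_posterior_draws <- function(theta, rho, labels, prior, chain) {
  structure(list(theta = theta, rho = rho, labels = labels, prior = prior,
                 chain = as.integer(chain)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws (%d chain(s)) over %d nodes, prior scale %.3g\n",
              dim(x$rho)[1], length(unique(x$chain)), dim(x$rho)[2],
              x$prior$prior_scale))
  invisible(x)
}

#' Number of pooled posterior draws
#' @param draws a `posterior_draws`.
#' @return integer count.
#' @export
n_draws_total <- function(draws) dim(draws$rho)[1]

#' Gibbs sampling of the precision matrix for one complete dataset
#'
#' @param dataset complete standardized matrix (columns mean 0 / sample SD 1,
#'   as produced by [npn_transform()]); must have more rows than columns.
#' @param prior a `prior_spec` with matching `k` (built automatically if a
#'   numeric scale is given).
#' @param n_draws retained draws (a warning is logged below 500).
#' @param burn_in discarded initial iterations.
#' @param seed integer seed.
#' @param chain_id chain label stored with the draws.
#' @return a `posterior_draws` object with `theta` and `rho` arrays
#'   (`n_draws x k x k`).
#' @export
sample_posterior <- function(dataset, prior = 0.2, n_draws = 10000L,
                             burn_in = 1000L, seed = 1L, chain_id = 1L) {
  x <- as.matrix(dataset)
  n <- nrow(x); k <- ncol(x)
  if (n <= k) stop("need more rows than columns to fit the GGM")
  if (is.numeric(prior)) prior <- prior_spec(prior, k)
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$k != k) stop("prior_spec k (", prior$k, ") does not match data (", k, ")")
  if (n_draws < 500L) warning("n_draws < 500: posterior summaries will be noisy")
  col_sd <- apply(x, 2L, stats::sd)
  if (any(abs(col_sd - 1) > 0.05) || any(abs(colMeans(x)) > 0.05))
    warning("columns do not look standardized; run npn_transform() first")

  s <- crossprod(x)
  b_inv <- diag(1 / prior$b, k)
  labels <- colnames(x) %||% paste0("V", seq_len(k))

  set.seed(substream_seed(seed, "gibbs", chain_id))
  theta <- chol_inv(s / n + diag(1e-6, k))
  total <- burn_in + n_draws
  theta_out <- array(NA_real_, c(n_draws, k, k), dimnames = list(NULL, labels, labels))
  rho_out <- theta_out
  for (it in seq_len(total)) {
    scale_phi <- tryCatch(chol_inv(theta + b_inv), error = function(e)
      stop("chain diverged at draw ", it, ": non-PD update (", conditionMessage(e), ")"))
    phi <- stats::rWishart(1L, prior$nu1 + prior$nu2, scale_phi)[, , 1]
    scale_theta <- tryCatch(chol_inv(s + phi), error = function(e)
      stop("chain diverged at draw ", it, ": non-PD update (", conditionMessage(e), ")"))
    theta <- stats::rWishart(1L, n + prior$nu1, scale_theta)[, , 1]
    if (it > burn_in) {
      d <- it - burn_in
      theta_out[d, , ] <- theta
      dd <- sqrt(diag(theta))
      r <- -theta / tcrossprod(dd)
      diag(r) <- 1
      rho_out[d, , ] <- r
    }
  }
  new_posterior_draws(theta_out, rho_out, labels, prior,
                      rep(chain_id, n_draws))
}

#' Pool posterior draws across imputed datasets
#'
#' Concatenates equally sized per-dataset chains with equal weight (the
#' posterior mixture over imputations).
#'
#' @param per_dataset list of `posterior_draws`, one per imputed dataset.
#' @return a single pooled `posterior_draws`.
#' @export
pool_imputations <- function(per_dataset) {
  stopifnot(length(per_dataset) >= 1L,
            all(vlapply(per_dataset, inherits, "posterior_draws")))
  if (length(per_dataset) == 1L) return(per_dataset[[1]])
  dims <- lapply(per_dataset, function(d) dim(d$rho))
  if (length(unique(vnapply(dims, function(d) d[2]))) != 1L ||
      length(unique(vnapply(dims, function(d) d[1]))) != 1L)
    stop("mismatched dimensions or unequal per-dataset draw counts")
  labels <- per_dataset[[1]]$labels
  if (!all(vlapply(per_dataset, function(d) identical(d$labels, labels))))
    stop("mismatched node labels across datasets")
  k <- dims[[1]][2]; nd <- dims[[1]][1]; m <- length(per_dataset)
  theta <- array(NA_real_, c(nd * m, k, k), dimnames = list(NULL, labels, labels))
  rho <- theta
  chain <- integer(nd * m)
  for (d in seq_len(m)) {
    idx <- (d - 1L) * nd + seq_len(nd)
    theta[idx, , ] <- per_dataset[[d]]$theta
    rho[idx, , ] <- per_dataset[[d]]$rho
    chain[idx] <- d
  }
  new_posterior_draws(theta, rho, labels, per_dataset[[1]]$prior, chain)
}

#' Fit the GGM to an imputed set, pooling across datasets
#'
#' Runs [npn_transform()] and [sample_posterior()] on every imputed dataset
#' and pools the chains. `n_draws` is the pooled total: each dataset
#' contributes `ceiling(n_draws / m)` retained draws.
#'
#' @param imp an `imputed_set`.
#' @param vars optional subset of variable names (e.g. the 7 traits).
#' @param prior_scale prior SD on the partial correlations.
#' @param n_draws pooled posterior draw count (study default 10,000).
#' @param burn_in per-chain burn-in.
#' @param seed integer seed.
#' @param residualize_covariates if TRUE, residualize each imputed dataset on
#'   age and sex before the nonparanormal transform (sensitivity analysis).
#' @return a pooled `posterior_draws`.
#' @export
fit_ggm <- function(imp, vars = NULL, prior_scale = 0.2, n_draws = 10000L,
                    burn_in = 1000L, seed = 1L, residualize_covariates = FALSE) {
  stopifnot(inherits(imp, "imputed_set"))
  m <- length(imp$datasets)
  per_chain <- as.integer(ceiling(n_draws / m))
  prior <- prior_spec(prior_scale,
                      k = length(vars %||% colnames(imp$datasets[[1]])))
  fits <- lapply(seq_len(m), function(d) {
    x <- imp$datasets[[d]]
    if (residualize_covariates)
      x <- residualize(x, imp$covariates, imp$schema)
    if (!is.null(vars)) x <- x[, vars, drop = FALSE]
    # the short-chain warning is per chain; silence it when the pooled
    # total is adequate
    withCallingHandlers(
      sample_posterior(npn_transform(x), prior, n_draws = per_chain,
                       burn_in = burn_in,
                       seed = substream_seed(seed, "ggm", d), chain_id = d),
      warning = function(w) {
        if (n_draws >= 500L && grepl("n_draws < 500", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  })
  pool_imputations(fits)
}

#' Standardized regression coefficients from posterior draws
#'
#' Per draw, `beta[i, j] = rho_ij * sqrt(theta_jj / theta_ii) = -theta_ij /
#' theta_ii`: the coefficient of node j in the regression of node i on all
#' other nodes (for unit-variance variables). Diagonal set to 0.
#'
#' @param draws a `posterior_draws`.
#' @return object of class `beta_draws`: array `n_draws x k x k` plus labels.
#' @export
beta_from_draws <- function(draws) {
  theta <- draws$theta
  nd <- dim(theta)[1]; k <- dim(theta)[2]
  beta <- theta
  for (d in seq_len(nd)) {
    th <- theta[d, , ]
    b <- -th / diag(th)   # rows scaled by 1/theta_ii
    diag(b) <- 0
    beta[d, , ] <- b
  }
  structure(list(beta = beta, labels = draws$labels), class = "beta_draws")
}

#' Bayesian R-squared for one node
#'
#' On the correlation scale the residual variance of the node-wise regression
#' is `1 / theta_nn`, so per draw `R2 = 1 - 1 / theta_nn`. Prior-dominated
#' draws with `theta_nn <= 1` are clipped at 0 (a message reports how many).
#'
#' @param draws a `posterior_draws` fitted to standardized data.
#' @param node node label or index.
#' @return list: `node`, `r2_mean`, `r2_cri` (central 95%), `r2_draws`.
#' @export
bayesian_r2 <- function(draws, node) {
  if (is.character(node)) node <- match(node, draws$labels)
  if (is.na(node)) stop("unknown node label")
  theta_nn <- draws$theta[, node, node]
  r2 <- 1 - 1 / theta_nn
  n_clip <- sum(r2 < 0)
  if (n_clip > 0) {
    message(n_clip, " prior-dominated draw(s) clipped at R2 = 0")
    r2[r2 < 0] <- 0
  }
  list(node = draws$labels[node], r2_mean = mean(r2),
       r2_cri = unname(stats::quantile(r2, c(0.025, 0.975))), r2_draws = r2)
}

split_rhat <- function(x, chain) {
  seqs <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2)
    seqs <- c(seqs, list(v[seq_len(h)], v[h + seq_len(h)]))
  }
  n <- min(lengths(seqs))
  seqs <- lapply(seqs, function(v) v[seq_len(n)])
  means <- vnapply(seqs, mean)
  vars <- vnapply(seqs, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w < 1e-300) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence diagnostics for the pooled chains
#'
#' Split-chain potential scale reduction factor for each requested edge's
#' partial-correlation draws; edges above 1.05 are flagged. Optionally
#' exports one PNG trace plot per requested edge.
#'
#' @param draws a `posterior_draws` (each imputed dataset is one chain;
#'   single chains are split in half).
#' @param edges data.frame with columns `i`, `j`; default all pairs.
#' @param dir if non-NULL, directory for `trace_<i>_<j>.png` files.
#' @return data.frame: `i`, `j`, `pair`, `rhat`, `flagged`.
#' @export
convergence_report <- function(draws, edges = NULL, dir = NULL) {
  k <- dim(draws$rho)[2]
  if (is.null(edges)) edges <- pairs_of(draws$labels)
  out <- data.frame(i = edges$i, j = edges$j,
                    pair = paste(draws$labels[edges$i], draws$labels[edges$j],
                                 sep = "--"),
                    rhat = NA_real_)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_len(nrow(out))) {
    x <- draws$rho[, out$i[r], out$j[r]]
    out$rhat[r] <- split_rhat(x, draws$chain)
    if (!is.null(dir)) {
      f <- file.path(dir, sprintf("trace_%d_%d.png", out$i[r], out$j[r]))
      grDevices::png(f, width = 700, height = 300)
      graphics::plot(x, type = "l", col = draws$chain,
                     xlab = "draw", ylab = "rho", main = out$pair[r])
      grDevices::dev.off()
    }
  }
  out$flagged <- out$rhat > 1.05
  out
}
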