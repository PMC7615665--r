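# fixtures are built in code; nothing is read from disk

# minimal hand-built cohort table on the cohort_A schema
make_tiny_table <- function(n = 10L, seed = 1L, family_id = NULL) {
  set.seed(seed)
  schema <- ndnet_schema("cohort_A")
  values <- sapply(seq_len(13), function(k)
    runif(n, schema$score_min[k], schema$score_max[k]))
  colnames(values) <- schema$name
  covariates <- data.frame(sex = rep_len(c(0, 1), n),
                           age_trait = rnorm(n, 8.5, 0.3),
                           age_stressor = rnorm(n, 9.3, 0.3),
                           age_depression = rnorm(n, 16, 0.3))
  cohort_table(values, covariates, "tiny", schema, family_id = family_id)
}

# imputed_set wrapper around complete matrices built in tests
make_imputed_set <- function(datasets, schema = ndnet_schema("cohort_A")) {
  n <- nrow(datasets[[1]])
  structure(list(datasets = datasets, cohort_id = "fixture",
                 config = imputation_config(m = length(datasets)),
                 covariates = data.frame(sex = rep(0, n), age_trait = rep(8, n),
                                         age_stressor = rep(9, n),
                                         age_depression = rep(16, n)),
                 schema = schema),
            class = "imputed_set")
}

# posterior_draws object with prescribed rho/theta arrays
make_draws <- function(theta, rho = NULL, labels = NULL, chain = NULL,
                       prior = prior_spec(0.2, dim(theta)[2])) {
  k <- dim(theta)[2]
  labels <- labels %||% paste0("V", seq_len(k))
  if (is.null(rho)) {
    rho <- theta
    for (d in seq_len(dim(theta)[1])) {
      dd <- sqrt(diag(theta[d, , ]))
      r <- -theta[d, , ] / tcrossprod(dd); diag(r) <- 1
      rho[d, , ] <- r
    }
  }
  dimnames(theta) <- dimnames(rho) <- list(NULL, labels, labels)
  ndnet:::new_posterior_draws(theta, rho, labels, prior,
                              chain %||% rep(1L, dim(theta)[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent partial-correlation oracle: conditional covariance of (i, j)
# given the rest, from the covariance matrix
pcor_oracle <- function(sigma, i, j) {
  rest <- setdiff(seq_len(nrow(sigma)), c(i, j))
  s_cond <- sigma[c(i, j), c(i, j)] -
    sigma[c(i, j), rest] %*% solve(sigma[rest, rest], sigma[rest, c(i, j)])
  cov2cor(s_cond)[1, 2]
}

# draws from the scaled Beta(delta/2, delta/2) prior on (-1, 1)
rscaled_beta <- function(n, delta) 2 * rbeta(n, delta / 2, delta / 2) - 1
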