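test_that("partial_from_precision matches the linear-algebra oracle", {
  expect_equal(partial_from_precision(diag(3)), diag(3), ignore_attr = TRUE)
  theta2 <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(partial_from_precision(theta2)[1, 2], 0.5)

  set.seed(8)
  a <- matrix(rnorm(25), 5)
  theta5 <- crossprod(a) + diag(0.5, 5)
  rho5 <- partial_from_precision(theta5)
  sigma5 <- solve(theta5)
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(abs(rho5[i, j] - pcor_oracle(sigma5, i, j)), 1e-12)

  expect_error(partial_from_precision(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("beta draws satisfy their algebraic identities", {
  set.seed(12)
  theta <- array(NA_real_, c(50, 4, 4))
  for (d in 1:50) {
    a <- matrix(rnorm(16), 4)
    theta[d, , ] <- crossprod(a) + diag(0.5, 4)
  }
  draws <- make_draws(theta, prior = prior_spec(0.2, 4))
  beta <- beta_from_draws(draws)
  for (d in c(1, 25, 50)) {
    th <- theta[d, , ]
    rho <- partial_from_precision(th)
    for (i in 1:4) for (j in setdiff(1:4, i)) {
      expect_lt(abs(beta$beta[d, i, j] - rho[i, j] * sqrt(th[j, j] / th[i, i])),
                1e-10)
      expect_lt(abs(beta$beta[d, i, j] / beta$beta[d, j, i] -
                    th[j, j] / th[i, i]), 1e-10)
      expect_equal(sign(beta$beta[d, i, j]), sign(rho[i, j]))
    }
  }
  # equal diagonals: beta equals rho
  th_eq <- diag(2); th_eq[1, 2] <- th_eq[2, 1] <- -0.3
  dr <- make_draws(array(th_eq, c(1, 2, 2)), prior = prior_spec(0.2, 2))
  expect_equal(beta_from_draws(dr)$beta[1, 1, 2], 0.3)
})

test_that("posterior-mean beta matches the closed-form regression oracle", {
  # population Sigma of a 4-variable standardized normal
  sigma <- diag(4)
  sigma[1, 2] <- sigma[2, 1] <- 0.5
  sigma[2, 3] <- sigma[3, 2] <- 0.4
  sigma[1, 3] <- sigma[3, 1] <- 0.3
  sigma[3, 4] <- sigma[4, 3] <- 0.35
  set.seed(19)
  x <- matrix(rnorm(20000 * 4), ncol = 4) %*% chol(sigma)
  x <- scale(x)
  colnames(x) <- paste0("V", 1:4)
  draws <- sample_posterior(x, prior_spec(0.2, 4), n_draws = 1500,
                            burn_in = 300, seed = 3)
  beta_mean <- apply(beta_from_draws(draws)$beta, c(2, 3), mean)
  for (i in 1:4) {
    ols <- solve(sigma[-i, -i], sigma[-i, i])  # all-others regression from Sigma
    expect_true(all(abs(beta_mean[i, -i] - ols) < 0.03))
  }
})

test_that("the sampler recovers null and planted partial correlations", {
  set.seed(23)
  x <- matrix(rnorm(5000 * 2), ncol = 2)
  x <- scale(x); colnames(x) <- c("a", "b")
  draws <- sample_posterior(x, prior_spec(0.2, 2), n_draws = 1200,
                            burn_in = 300, seed = 5)
  expect_lt(abs(mean(draws$rho[, 1, 2])), 0.03)

  theta3 <- diag(3)
  theta3[1, 2] <- theta3[2, 1] <- -0.3   # rho_12 = 0.3
  theta3[2, 3] <- theta3[3, 2] <- 0.2    # rho_23 = -0.2
  set.seed(24)
  y <- matrix(rnorm(5000 * 3), ncol = 3) %*% chol(solve(theta3))
  y <- scale(y); colnames(y) <- c("x1", "x2", "x3")
  dr3 <- sample_posterior(y, prior_spec(0.2, 3), n_draws = 1500,
                          burn_in = 300, seed = 6)
  rho_mean <- apply(dr3$rho, c(2, 3), mean)
  expect_true(all(abs(rho_mean - partial_from_precision(theta3)) < 0.04))
})

test_that("posterior mean matches an importance-sampling oracle on 3 nodes", {
  theta3 <- diag(3)
  theta3[1, 2] <- theta3[2, 1] <- -0.25
  set.seed(31)
  n <- 2000
  y <- matrix(rnorm(n * 3), ncol = 3) %*% chol(solve(theta3))
  y <- scale(y); colnames(y) <- c("x1", "x2", "x3")
  prior <- prior_spec(0.2, 3)
  draws <- sample_posterior(y, prior, n_draws = 4000, burn_in = 500, seed = 7)
  gibbs_mean <- mean(draws$rho[, 1, 2])

  # independent oracle: importance sampling against the matrix-F posterior
  # with Phi integrated out,
  #   p(Theta) propto |Theta|^((n+nu1-k-1)/2) exp(-tr(S Theta)/2)
  #                   |Theta + B^-1|^(-(nu1+nu2)/2).
  # The proposal Wishart absorbs the linearisation of the log-determinant
  # term at the fixed point Phi_hat, leaving only curvature in the weights.
  s <- crossprod(y)
  b_inv_mat <- diag(1 / prior$b, 3)
  nu12 <- prior$nu1 + prior$nu2
  theta_hat <- (n + prior$nu1) * solve(s + diag(prior$nu2 * prior$b, 3))
  for (t in 1:25) {
    phi_hat <- nu12 * solve(theta_hat + b_inv_mat)
    theta_hat <- (n + prior$nu1) * solve(s + phi_hat)
  }
  prop_scale <- solve(s + phi_hat)
  set.seed(77)
  m_is <- 6000
  th_draws <- rWishart(m_is, n + prior$nu1, prop_scale)
  logw <- numeric(m_is); rho12 <- numeric(m_is)
  for (d in seq_len(m_is)) {
    th <- th_draws[, , d]
    logw[d] <- sum(phi_hat * th) / 2 -
      nu12 / 2 * determinant(th + b_inv_mat)$modulus
    rho12[d] <- -th[1, 2] / sqrt(th[1, 1] * th[2, 2])
  }
  w <- exp(logw - max(logw))
  expect_gt(sum(w)^2 / sum(w^2), 500)   # effective sample size sanity check
  is_mean <- sum(w * rho12) / sum(w)
  expect_lt(abs(gibbs_mean - is_mean), 0.02)
})

test_that("pooling concatenates equally weighted chains", {
  th_a <- array(rep(diag(2), 10), c(2, 2, 10))
  mk <- function(v) {
    th <- array(NA_real_, c(10, 2, 2))
    for (d in 1:10) { m <- diag(2); m[1, 2] <- m[2, 1] <- v; th[d, , ] <- m }
    make_draws(th, prior = prior_spec(0.2, 2))
  }
  a <- mk(-0.2); b <- mk(-0.4)   # rho 0.2 and 0.4
  expect_identical(pool_imputations(list(a)), a)
  pooled <- pool_imputations(list(a, b))
  expect_equal(n_draws_total(pooled), 20L)
  expect_equal(mean(pooled$rho[, 1, 2]), (0.2 + 0.4) / 2)
  expect_equal(sort(unique(pooled$chain)), c(1L, 2L))

  c3 <- mk(-0.2); c3$rho <- c3$rho[1:5, , , drop = FALSE]
  c3$theta <- c3$theta[1:5, , , drop = FALSE]; c3$chain <- c3$chain[1:5]
  expect_error(pool_imputations(list(a, c3)), "mismatched")
})

test_that("bayesian R2 follows the precision-diagonal closed form", {
  th_diag <- array(rep(diag(c(1, 1, 1)), 5), c(3, 3, 5))
  th <- array(NA_real_, c(5, 3, 3))
  for (d in 1:5) th[d, , ] <- diag(3)
  dr <- make_draws(th, prior = prior_spec(0.2, 3))
  r2 <- suppressMessages(bayesian_r2(dr, 1))
  expect_equal(r2$r2_mean, 0)

  # 2-node system with population correlation r: R2 = r^2
  r <- 0.6
  set.seed(41)
  x <- matrix(rnorm(5000 * 2), ncol = 2) %*% chol(matrix(c(1, r, r, 1), 2))
  x <- scale(x); colnames(x) <- c("a", "b")
  draws <- sample_posterior(x, prior_spec(0.2, 2), n_draws = 1200,
                            burn_in = 300, seed = 9)
  out <- bayesian_r2(draws, "a")
  expect_lt(abs(out$r2_mean - r^2), 0.03)
  expect_true(out$r2_cri[1] <= out$r2_mean && out$r2_mean <= out$r2_cri[2])
  expect_true(out$r2_cri[1] >= 0 && out$r2_cri[2] < 1)
})

test_that("convergence report computes split-chain diagnostics and traces", {
  set.seed(51)
  k <- 3
  th <- array(NA_real_, c(2000, k, k))
  rho <- array(NA_real_, c(2000, k, k))
  for (d in 1:2000) { th[d, , ] <- diag(k); rho[d, , ] <- diag(k) }
  rho[, 1, 2] <- rho[, 2, 1] <- rnorm(2000)            # white noise: converged
  rho[, 1, 3] <- rho[, 3, 1] <- seq(0, 3, length.out = 2000)  # trend: flagged
  dr <- make_draws(th, rho = rho, chain = rep(1:2, each = 1000),
                   prior = prior_spec(0.2, k))
  dir <- withr::local_tempdir()
  rep_ <- convergence_report(dr, edges = data.frame(i = c(1, 1), j = c(2, 3)),
                             dir = dir)
  expect_gte(rep_$rhat[1], 1.0 - 1e-8)
  expect_lt(rep_$rhat[1], 1.02)
  expect_false(rep_$flagged[1])
  expect_true(rep_$flagged[2])
  expect_length(list.files(dir, pattern = "^trace_.*png$"), 2L)
})

test_that("relabeling nodes permutes classifications consistently", {
  set.seed(61)
  x <- matrix(rnorm(1500 * 3), ncol = 3)
  x[, 2] <- 0.5 * x[, 1] + sqrt(0.75) * x[, 2]
  x <- scale(x); colnames(x) <- c("a", "b", "c")
  draws <- sample_posterior(x, prior_spec(0.2, 3), n_draws = 1500,
                            burn_in = 300, seed = 11)
  perm <- c(3, 1, 2)
  permuted <- draws
  permuted$theta <- draws$theta[, perm, perm]
  permuted$rho <- draws$rho[, perm, perm]
  permuted$labels <- draws$labels[perm]
  dec <- classify_edges(draws)
  dec_p <- classify_edges(permuted)
  for (r in seq_len(nrow(dec))) {
    lab <- strsplit(dec$pair[r], "--")[[1]]
    match_row <- which(vapply(strsplit(dec_p$pair, "--"), function(v)
      setequal(v, lab), logical(1)))
    expect_equal(dec_p$status[match_row], dec$status[r])
    expect_equal(dec_p$rho_mean[match_row], dec$rho_mean[r], tolerance = 1e-12)
  }
})
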