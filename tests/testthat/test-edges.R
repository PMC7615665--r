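test_that("Savage-Dickey BF behaves at its limiting cases", {
  prior <- prior_spec(0.2, 13)
  set.seed(71)
  # draws resampled from the prior itself: no information, BF near 1
  prior_draws <- rscaled_beta(20000, prior$delta)
  bf <- savage_dickey_bf(prior_draws, prior)
  expect_gt(bf$bf01, 0.8)
  expect_lt(bf$bf01, 1.25)
  expect_equal(bf$bf10, 1 / bf$bf01)

  # posterior concentrated far from 0: overwhelming evidence for association
  conc <- rnorm(5000, 0.5, 0.02)
  bf2 <- savage_dickey_bf(conc, prior)
  expect_gt(bf2$bf10, 100)
  expect_true(bf2$floored)  # density at 0 vanishes -> clamped at the floor

  # normal cross-check mode agrees with the analytic normal ordinate
  norm_draws <- rnorm(50000, 0.05, 0.05)
  bf3 <- savage_dickey_bf(norm_draws, prior, method = "normal")
  oracle <- dnorm(0, mean(norm_draws), sd(norm_draws)) / prior_density0(prior)
  expect_equal(bf3$bf01, oracle, tolerance = 1e-12)
  bf3k <- savage_dickey_bf(norm_draws, prior, method = "kde")
  expect_lt(abs(bf3k$bf01 / oracle - 1), 0.05)

  expect_warning(savage_dickey_bf(rnorm(100), prior), "1,000")
})

test_that("three-way classification follows the BF rules and is exhaustive", {
  set.seed(72)
  k <- 3
  th <- array(NA_real_, c(4000, k, k)); rho <- th
  for (d in 1:4000) { th[d, , ] <- diag(k); rho[d, , ] <- diag(k) }
  prior <- prior_spec(0.2, k)
  rho[, 1, 2] <- rho[, 2, 1] <- rnorm(4000, 0, 0.01)        # tight at 0
  rho[, 1, 3] <- rho[, 3, 1] <- rnorm(4000, 0.4, 0.02)      # tight at 0.4
  rho[, 2, 3] <- rho[, 3, 2] <- rscaled_beta(4000, prior$delta)  # prior-like
  dr <- make_draws(th, rho = rho, prior = prior)
  dec <- classify_edges(dr)
  get <- function(p) dec[dec$pair == p, ]
  expect_equal(get("V1--V2")$status, "independent")
  expect_gte(get("V1--V2")$bf01, 3)
  expect_equal(get("V1--V3")$status, "associated")
  expect_gte(get("V1--V3")$bf10, 3)
  expect_equal(get("V2--V3")$status, "ambiguous")
  expect_lt(get("V2--V3")$bf01, 3)
  expect_lt(get("V2--V3")$bf10, 3)
  # exhaustive and mutually exclusive by construction of the rule
  expect_true(all(dec$status %in% c("associated", "independent", "ambiguous")))
  expect_true(all(abs(dec$bf10 - 1 / dec$bf01) < 1e-9))
  # credible intervals bracket the posterior mean
  expect_true(all(dec$cri_low <= dec$rho_mean & dec$rho_mean <= dec$cri_high))
})

test_that("replication statuses implement the cross-cohort rules", {
  mk <- function(status, rho) data.frame(
    pair = paste0("p", seq_along(status)), i = seq_along(status),
    j = seq_along(status) + 1, bf01 = 1, bf10 = 1,
    rho_mean = rho, cri_low = rho - 0.1, cri_high = rho + 0.1,
    status = status, stringsAsFactors = FALSE)
  a <- mk(c("associated", "independent", "associated", "associated", "ambiguous",
            "independent"),
          c(0.3, 0.0, 0.2, 0.25, 0.1, 0.0))
  b <- mk(c("associated", "independent", "independent", "associated", "associated",
            "ambiguous"),
          c(0.25, 0.0, 0.1, -0.2, 0.15, 0.0))
  repl <- replicate_edges(a, b)
  expect_equal(repl$replication,
               c("replicated_association",   # associated both, same sign
                 "replicated_independence",  # independent both
                 "discordant",               # associated vs independent
                 "discordant",               # both associated, conflicting sign
                 "unreplicated",             # ambiguous in one cohort
                 "unreplicated"))
  b_bad <- b; b_bad$pair[1] <- "other"
  expect_error(replicate_edges(a, b_bad), "pair sets")
})

test_that("network density reproduces the study's percentage arithmetic", {
  mk_repl <- function(n_assoc, n_total, count = "replicated_association") {
    data.frame(pair = paste0("p", seq_len(n_total)),
               i = 1, j = 2, status_a = "x", status_b = "x",
               sign_a = 1, sign_b = 1, rho_mean_a = 0.1, rho_mean_b = 0.1,
               replication = rep(c(count, "unreplicated"),
                                 c(n_assoc, n_total - n_assoc)),
               stringsAsFactors = FALSE) -> d
    class(d) <- c("replication_summary", class(d))
    d
  }
  pair_set <- function(n) data.frame(pair = paste0("p", seq_len(n)))
  expect_equal(network_density(mk_repl(11, 21), pair_set(21))$density_pct, 52)
  expect_equal(network_density(mk_repl(2, 21), pair_set(21))$density_pct, 9.5)
  expect_equal(network_density(mk_repl(12, 21), pair_set(21))$density_pct, 57)
  expect_equal(network_density(mk_repl(6, 21), pair_set(21))$density_pct, 29)
  expect_equal(network_density(mk_repl(2, 9), pair_set(9))$density_pct, 22)
  expect_equal(network_density(mk_repl(0, 13), pair_set(13))$density_pct, 0)
  ind <- mk_repl(3, 21, count = "replicated_independence")
  expect_equal(network_density(ind, pair_set(21),
                               count = "replicated_independence")$density_pct, 14)
})

test_that("adjacency similarity matches the vectorized correlation oracle", {
  mk <- function(rho_vals, status = "associated") data.frame(
    pair = paste0("p", seq_along(rho_vals)), i = seq_along(rho_vals), j = 2,
    bf01 = 0.1, bf10 = 10, rho_mean = rho_vals,
    cri_low = rho_vals - 0.1, cri_high = rho_vals + 0.1,
    status = status, stringsAsFactors = FALSE)
  set.seed(81)
  va <- runif(21, -0.5, 0.5); vb <- va + rnorm(21, 0, 0.1)
  a <- mk(va); b <- mk(vb)
  expect_equal(adjacency_similarity(a, b, replicated_only = FALSE),
               cor(va, vb), tolerance = 1e-12)
  # replicated-only mode drops sign-discordant pairs before correlating
  repl <- replicate_edges(a, b)
  keep <- repl$replication == "replicated_association"
  expect_equal(adjacency_similarity(a, b), cor(va[keep], vb[keep]),
               tolerance = 1e-12)
  expect_equal(adjacency_similarity(a, a), 1)
  neg <- mk(-va)
  expect_equal(adjacency_similarity(a, neg, replicated_only = FALSE), -1)
  small <- mk(va[1:2])
  expect_error(adjacency_similarity(small, mk(vb[1:2])), "fewer than 3")
})

test_that("mediation index multiplies the standardized path coefficients", {
  k <- 3
  beta_arr <- array(0, c(100, k, k))
  beta_arr[, 3, 2] <- 0.4   # y <- m
  bd <- structure(list(beta = beta_arr, labels = c("x", "m", "y")),
                  class = "beta_draws")
  est <- mediation_index(bd, "x", "m", "y")   # beta(m <- x) is 0
  expect_equal(est$ab_mean, 0)
  expect_equal(est$ab_cri, c(0, 0))

  beta_arr[, 2, 1] <- rnorm(100, 0.3, 0.05)
  bd2 <- structure(list(beta = beta_arr, labels = c("x", "m", "y")),
                   class = "beta_draws")
  est2 <- mediation_index(bd2, "x", "m", "y")
  expect_equal(est2$ab_draws, beta_arr[, 2, 1] * 0.4)
  expect_true(est2$ab_cri[1] <= est2$ab_mean && est2$ab_mean <= est2$ab_cri[2])
  expect_error(mediation_index(bd2, "x", "x", "y"), "distinct")
  expect_error(mediation_index(bd2, "x", "m", "zz"), "unknown")
})
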