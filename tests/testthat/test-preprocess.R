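test_that("imputation preserves observed cells and is deterministic", {
  tb <- simulate_cohort(default_planted_network("paper_like"),
                        ndnet_schema("cohort_A"),
                        cohort_sim_config(300, seed = 2, missing_rate = 0.2,
                                          all_trait_missing_frac = 0))
  tb <- apply_exclusions(tb)
  imp <- impute(tb, imputation_config(m = 3, max_iter = 3, seed = 7))
  expect_length(imp$datasets, 3L)
  obs <- !is.na(tb$values)
  for (d in imp$datasets) {
    expect_false(anyNA(d))
    expect_equal(d[obs], tb$values[obs])
  }
  # draws differ across datasets but the seed pins the whole set
  expect_false(identical(imp$datasets[[1]], imp$datasets[[2]]))
  imp2 <- impute(tb, imputation_config(m = 3, max_iter = 3, seed = 7))
  expect_identical(imp$datasets, imp2$datasets)
})

test_that("a complete table imputes to m identical copies", {
  tb <- simulate_cohort(default_planted_network("null"),
                        ndnet_schema("cohort_A"),
                        cohort_sim_config(80, seed = 4, missing_rate = 0,
                                          all_trait_missing_frac = 0))
  imp <- impute(tb, imputation_config(m = 3, max_iter = 2, seed = 1))
  expect_identical(imp$datasets[[1]], tb$values)
  expect_identical(imp$datasets[[2]], imp$datasets[[3]])
})

test_that("imputation under MCAR recovers complete-data column means", {
  net <- default_planted_network("paper_like")
  schema <- ndnet_schema("cohort_A")
  tb <- simulate_cohort(net, schema,
                        cohort_sim_config(5000, seed = 31, missing_rate = 0,
                                          all_trait_missing_frac = 0))
  complete_means <- colMeans(tb$values)
  complete_sds <- apply(tb$values, 2, sd)
  set.seed(99)
  masked <- tb
  masked$values[matrix(runif(length(tb$values)) < 0.2,
                       nrow(tb$values))] <- NA_real_
  masked <- apply_exclusions(masked)
  imp <- impute(masked, imputation_config(m = 3, max_iter = 4, seed = 8))
  pooled_means <- colMeans(Reduce(`+`, imp$datasets) / length(imp$datasets))
  expect_true(all(abs(pooled_means - complete_means) < 0.05 * complete_sds))

  masked$values[, "dep_21"] <- NA_real_
  expect_error(impute(masked, imputation_config(m = 1, seed = 1)),
               "zero observed")
})

test_that("npn_shrunken matches its closed forms and contracts", {
  # n = 2: qnorm(1/3), qnorm(2/3) standardized to unit sample SD
  expect_equal(npn_shrunken(c(5, 9)), c(-sqrt(2) / 2, sqrt(2) / 2))

  set.seed(1)
  x <- rexp(500)^2
  out <- npn_shrunken(x)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sd(out), 1, tolerance = 1e-9)
  expect_equal(rank(out), rank(x))
  # rank invariance under any strictly increasing transform
  expect_equal(npn_shrunken(exp(x)), out)
  expect_equal(npn_shrunken(rank(x)), out)

  expect_error(npn_shrunken(rep(1, 10)), "constant")
  expect_error(npn_shrunken(c(1, NA, 3)), "complete")

  # Glivenko-Cantelli: near identity on a large standard-normal sample in the
  # bulk of the distribution (the normal-quantile map amplifies the empirical
  # CDF error without bound in the extreme tails, so the sup is taken over
  # |z| <= 2)
  set.seed(2)
  z <- rnorm(10000)
  d <- abs(npn_shrunken(z) - z)
  expect_lt(max(d[abs(z) <= 2]), 0.1)
  expect_lt(median(d), 0.02)
})

test_that("residualize produces standardized residuals orthogonal to covariates", {
  set.seed(6)
  n <- 200
  cov_df <- data.frame(sex = rbinom(n, 1, 0.5), age_trait = rnorm(n, 8),
                       age_stressor = rnorm(n, 9), age_depression = rnorm(n, 16))
  schema <- ndnet_schema("cohort_A")
  x <- matrix(rnorm(n * 13), n, 13, dimnames = list(NULL, schema$name))
  x[, 1] <- x[, 1] + 0.8 * cov_df$age_trait + 0.5 * cov_df$sex
  out <- residualize(x, cov_df, schema)
  expect_lt(abs(cor(out[, 1], cov_df$age_trait)), 1e-10)
  expect_lt(abs(cor(out[, 1], cov_df$sex)), 1e-10)
  expect_equal(apply(out, 2, sd), rep(1, 13), ignore_attr = TRUE)
  # covariates orthogonal to a column: unchanged up to re-standardization
  expect_gt(cor(out[, 2], x[, 2]), 0.99)

  x_bad <- x
  x_bad[, 3] <- 2 * cov_df$age_trait - 1
  expect_error(residualize(x_bad, cov_df, schema), "exact linear function")

  cov_bad <- cov_df
  cov_bad$age_trait <- 5   # constant age: collinear with the intercept
  expect_error(residualize(x, cov_bad, schema), "collinear")
})

test_that("zero-order screen pools by Rubin's rules on the Fisher-z scale", {
  expect_equal(bonferroni_threshold(0.05, 21), 0.05 / 21)

  set.seed(17)
  n <- 10000
  schema <- ndnet_schema("cohort_A")
  x <- matrix(rnorm(n * 13), n, 13, dimnames = list(NULL, schema$name))
  x[, "dep_12"] <- 0.3 * x[, "autistic"] + sqrt(1 - 0.09) * rnorm(n)
  imp1 <- make_imputed_set(list(x))
  sc1 <- zero_order_screen(imp1)
  expect_equal(attr(sc1, "threshold"), 0.05 / 21)
  # m = 1: pooled r equals the plain Pearson correlation
  row <- sc1[sc1$pair == "autistic--dep_12", ]
  expect_equal(row$r_pooled, cor(x[, "autistic"], x[, "dep_12"]),
               tolerance = 1e-12)
  expect_lt(abs(row$r_pooled - 0.3), 0.02)
  expect_true(row$significant)
  null_row <- sc1[sc1$pair == "hyperactive_impulsive--dep_16", ]
  expect_false(null_row$significant)

  # m = 3 with perturbed copies: between-imputation variance widens p
  imps <- lapply(1:3, function(d) {
    y <- x; set.seed(d); y[, "dep_12"] <- y[, "dep_12"] + rnorm(n, 0, 0.4); y
  })
  sc3 <- zero_order_screen(make_imputed_set(imps))
  expect_true(all(abs(sc3$r_pooled) <= 1))
  expect_equal(nrow(sc3), 21L)
})
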