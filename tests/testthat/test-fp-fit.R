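test_that("noiseless data recovers the generating coefficients exactly", {
  tb <- mk_fp_cohort(n = 400, powers = 1, coefs = -0.01, noise_sd = 0,
                     seed = 2)
  fit <- fit_fp(tb, "y", powers = 1)
  expect_lt(fit$rss, 1e-18)
  expect_equal(unname(fit$coefficients["age^1"]), -0.01, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["sex(female)"]), 0.02,
               tolerance = 1e-10)
  expect_equal(variance_explained(fit), 1, tolerance = 1e-12)
})

test_that("OLS matches a brute-force normal-equations oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(20:50, 1)
    tb <- mk_fp_cohort(n = n, powers = c(0, 1), coefs = c(-0.1, -0.002),
                       noise_sd = 0.1, seed = i)
    pw <- list(c(1), c(0, 2), c(-0.5, -0.5))[[1 + i %% 3]]
    fit <- fit_fp(tb, "y", pw)
    X <- cbind(fp_basis(tb$age, pw),
               `sex(female)` = as.numeric(tb$sex == "female"))
    Xc <- sweep(X, 2, colMeans(X))
    yc <- tb$y - mean(tb$y)
    beta <- solve(crossprod(Xc), crossprod(Xc, yc))
    expect_equal(unname(fit$coefficients), unname(drop(beta)),
                 tolerance = 1e-8)
    expect_equal(fit$rss, sum((yc - Xc %*% beta)^2), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail loudly", {
  tb <- mk_fp_cohort(n = 100, noise_sd = 0.1)
  tb$age <- rep(20, 100)   # constant age collapses all basis columns
  expect_error(fit_fp(tb, "y", c(0, 1)), "collinear")
})

test_that("partial F statistic matches the textbook formula", {
  # RSS_s = 10, RSS_b = 8, df gain 2, denominator df 100 -> F = 12.5
  small <- structure(list(rss = 10, df_model = 2, n = 105),
                     class = "fp_fit")
  big <- structure(list(rss = 8, df_model = 4, n = 105), class = "fp_fit")
  ft <- partial_f_test(small, big)
  expect_equal(ft$F, 12.5)
  expect_equal(ft$p, pf(12.5, 2, 100, lower.tail = FALSE))
  # no improvement: F = 0, p = 1
  same <- structure(list(rss = 10, df_model = 3, n = 105),
                    class = "fp_fit")
  ft0 <- partial_f_test(small, same)
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p, 1)
  expect_error(partial_f_test(big, small), "nested")
  expect_error(partial_f_test(small,
                              structure(list(rss = 8, df_model = 4, n = 99),
                                        class = "fp_fit")), "unequal n")
})

test_that("cluster-robust SEs exceed naive SEs under site random effects", {
  # sites occupy distinct age windows, so site intercepts project onto the
  # age column and inflate its true sampling variance
  set.seed(8)
  n_sites <- 12
  n_per <- 250
  lo <- seq(5, 60, length.out = n_sites)
  gam <- rnorm(n_sites, 0, 0.15)
  df <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
    age <- runif(n_per, lo[i], lo[i] + 25)
    data.frame(subject_id = paste0("S", i, "_", seq_len(n_per)),
               site_id = paste0("S", i),
               sex = sample(c("male", "female"), n_per, TRUE), age = age,
               y = 3 - 0.01 * age + gam[i] + rnorm(n_per, sd = 0.1),
               stringsAsFactors = FALSE)
  }))
  tb <- structure(df, regions = "y", age_bounds = c(3, 90),
                  class = c("cohort_table", "data.frame"))
  fit <- fit_fp(tb, "y", powers = 1)
  expect_gt(sqrt(fit$vcov_robust["age^1", "age^1"]),
            sqrt(fit$vcov_naive["age^1", "age^1"]))
  expect_true(isSymmetric(fit$vcov_robust, tol = 1e-10))
  expect_true(all(eigen(fit$vcov_robust, only.values = TRUE)$values > -1e-12))
})

test_that("coefficient estimates are calibrated against robust SEs", {
  hits <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    tb <- mk_fp_cohort(n = 2000, powers = c(0, 1, 1),
                       coefs = c(-0.2, -0.004, 0.0004),
                       intercept = 3.4, noise_sd = 0.15, seed = 1000 + s,
                       n_sites = 8)
    fit <- fit_fp(tb, "y", c(0, 1, 1))
    se <- sqrt(diag(fit$vcov_robust))[1:3]
    ok <- abs(fit$coefficients[1:3] - c(-0.2, -0.004, 0.0004)) <= 3 * se
    hits <- hits + all(ok)
  }
  expect_gte(hits, 0.95 * n_rep)
})

test_that("age at maximum follows the fitted curve and tie-break rule", {
  tb <- mk_fp_cohort(n = 500, powers = 1, coefs = -0.01, noise_sd = 0,
                     seed = 4, age_range = c(3, 90))
  fit <- fit_fp(tb, "y", powers = 1)
  expect_equal(age_at_max(fit, c(3, 90)), 3)
  # constant curve: tie broken toward the youngest age
  tbc <- mk_fp_cohort(n = 500, powers = 1, coefs = 0, noise_sd = 0,
                      seed = 4, age_range = c(3, 90))
  fitc <- fit_fp(tbc, "y", powers = 1)
  expect_equal(age_at_max(fitc, c(3, 90)), 3)
  expect_error(age_at_max(fit, c(0, 90)), "positive")
  # inverse-U with analytic vertex at 67.5
  c1 <- 0.006
  tbu <- mk_fp_cohort(n = 2000, powers = c(1, 2),
                      coefs = c(c1, -c1 / (2 * 67.5)),
                      intercept = 2.8, noise_sd = 0, seed = 5)
  fitu <- fit_fp(tbu, "y", c(1, 2))
  expect_lt(abs(age_at_max(fitu, c(3, 90)) - 67.5), 0.1 + 1e-9)
})

test_that("variance explained behaves as a proper R-squared", {
  tb <- mk_fp_cohort(n = 5000, powers = 1, coefs = 0, noise_sd = 0.15,
                     seed = 6, sex_effect = 0)
  fit <- fit_fp(tb, "y", powers = 1, sex_covariate = FALSE)
  expect_lt(variance_explained(fit), 0.01)   # age-independent region
  tb2 <- tb
  tb2$y <- tb$y + 5
  fit2 <- fit_fp(tb2, "y", powers = 1, sex_covariate = FALSE)
  expect_lt(abs(variance_explained(fit) - variance_explained(fit2)), 1e-12)
})
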