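test_that("a single site is left untouched", {
  tb <- mk_cohort(300, "A")
  m <- fit_combat(tb)
  expect_true(all(abs(m$gamma_star) < 1e-12))
  expect_true(all(abs(m$delta_star - 1) < 1e-12))
  h <- apply_combat(m, tb)
  expect_equal(as.data.frame(h), as.data.frame(tb), tolerance = 1e-12)
})

test_that("a pure location shift is removed exactly without covariates", {
  set.seed(10)
  base <- rnorm(200, 3, 0.1)
  df <- data.frame(subject_id = paste0("s", 1:400),
                   site_id = rep(c("A", "B"), each = 200),
                   sex = "female", age = rep(runif(200, 10, 80), 2),
                   r1 = c(base, base + 0.3), stringsAsFactors = FALSE)
  tb <- structure(df, regions = "r1", age_bounds = c(3, 90),
                  class = c("cohort_table", "data.frame"))
  m <- fit_combat(tb, design = combat_design(NULL, sex = FALSE), eb = FALSE)
  h <- apply_combat(m, tb)
  mns <- tapply(h$r1, h$site_id, mean)
  expect_lt(abs(mns[["A"]] - mns[["B"]]), 1e-10)
})

test_that("a pure scale difference is equalized exactly", {
  set.seed(11)
  e <- rnorm(300)
  df <- data.frame(subject_id = paste0("s", 1:600),
                   site_id = rep(c("A", "B"), each = 300),
                   sex = "female", age = 40,
                   r1 = c(3 + 0.1 * e, 3 + 0.2 * e),
                   stringsAsFactors = FALSE)
  tb <- structure(df, regions = "r1", age_bounds = c(3, 90),
                  class = c("cohort_table", "data.frame"))
  m <- fit_combat(tb, design = combat_design(NULL, sex = FALSE), eb = FALSE)
  h <- apply_combat(m, tb)
  sds <- tapply(h$r1, h$site_id, sd)
  expect_lt(abs(sds[["A"]] / sds[["B"]] - 1), 1e-10)
})

test_that("harmonizing the fitting table is idempotent", {
  tb <- mk_cohort(250, c("A", "B"), gammas = c(0, 0.3), seed = 3)
  # exact without covariates
  des <- combat_design(NULL, sex = FALSE)
  h <- apply_combat(fit_combat(tb, design = des, eb = FALSE), tb)
  m2 <- fit_combat(h, design = des, eb = FALSE)
  expect_lt(max(abs(m2$gamma_star)), 1e-6)
  expect_lt(max(abs(m2$delta_star - 1)), 1e-6)
  # with covariates and EB shrinkage, residual site effects are tiny on the
  # data scale but not numerically zero
  h2 <- apply_combat(fit_combat(tb), tb)
  m3 <- fit_combat(h2)
  expect_lt(max(abs(m3$gamma_star)), 0.05)
})

test_that("errors: unknown sites, undersized sites, collinear designs", {
  tb <- mk_cohort(100, c("A", "B"))
  m <- fit_combat(tb)
  tb2 <- tb
  tb2$site_id[1] <- "Z"
  expect_error(apply_combat(m, tb2), "Z")
  small <- tb[-(2:100), ]  # site A keeps 1 subject
  expect_error(fit_combat(small), "at least 2")
  tb3 <- mk_cohort(100, c("A", "B"))
  tb3$age <- ifelse(tb3$site_id == "A", 20, 60)  # age == site indicator
  expect_error(fit_combat(tb3, design = combat_design(1, sex = FALSE)),
               "collinear")
})

test_that("site mean variance collapses while the age slope survives", {
  tb <- mk_cohort(600, c("A", "B", "C"), gammas = c(-0.3, 0, 0.3), seed = 6)
  h <- apply_combat(fit_combat(tb), tb)
  for (rg in c("r1", "r2")) {
    pre <- var(tapply(tb[[rg]], tb$site_id, mean))
    post <- var(tapply(h[[rg]], h$site_id, mean))
    expect_lt(post / pre, 0.1)
  }
  sl <- coef(lm(r1 ~ age + sex, data = h))[["age"]]
  expect_lt(abs(sl / -0.01 - 1), 0.05)
  expect_equal(nrow(h), nrow(tb))
  expect_identical(h$age, tb$age)
  expect_identical(h$sex, tb$sex)
})

test_that("EB estimates shrink toward the prior mean", {
  tb <- mk_cohort(80, c("A", "B", "C"), gammas = c(-0.2, 0, 0.2), seed = 9)
  m_raw <- fit_combat(tb, eb = FALSE)
  m_eb <- fit_combat(tb, eb = TRUE)
  for (i in seq_along(m_eb$sites)) {
    gbar <- m_eb$priors[[i]]$gamma_bar
    lo <- pmin(m_raw$gamma_star[i, ], gbar) - 1e-9
    hi <- pmax(m_raw$gamma_star[i, ], gbar) + 1e-9
    expect_true(all(m_eb$gamma_star[i, ] >= lo &
                      m_eb$gamma_star[i, ] <= hi))
  }
})

test_that("row order does not affect the harmonized values", {
  tb <- mk_cohort(150, c("A", "B"), gammas = c(0, 0.25), seed = 13)
  m <- fit_combat(tb)
  h <- apply_combat(m, tb)
  perm <- sample(nrow(tb))
  hp <- apply_combat(m, tb[perm, ])
  expect_equal(hp$r1, h$r1[perm], tolerance = 1e-12)
})

test_that("a fitted model harmonizes new rows from known sites", {
  tb <- mk_cohort(400, c("A", "B"), gammas = c(0, 0.3), seed = 21)
  half <- seq_len(nrow(tb)) %% 2 == 0
  m <- fit_combat(tb[half, ])
  h_new <- apply_combat(m, tb[!half, ])
  mns <- tapply(h_new$r1, h_new$site_id, mean)
  expect_lt(abs(mns[["A"]] - mns[["B"]]), 0.05)
})

test_that("the in-package fit agrees with the reference implementation", {
  skip_if_not_installed("sva")
  tb <- mk_cohort(400, c("A", "B", "C"), gammas = c(-0.2, 0, 0.2),
                  deltas = c(0.8, 1, 1.3), seed = 5)
  des <- combat_design(age_powers = 1, sex = TRUE)
  h <- apply_combat(fit_combat(tb, design = des), tb)
  dat <- t(as.matrix(tb[, cohort_regions(tb)]))
  mod <- stats::model.matrix(~ age + I(sex == "female"),
                             data = as.data.frame(tb))
  ref <- t(suppressMessages(sva::ComBat(dat, batch = tb$site_id,
                                        mod = mod)))
  # conventions differ only in an n vs n-1 variance denominator
  expect_lt(max(abs(ref - as.matrix(h[, cohort_regions(tb)]))), 0.005)
})
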