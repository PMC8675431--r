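test_that("trajectory values evaluate the FP mean exactly", {
  sp <- trajectory_spec("r", powers = 1, coefficients = -0.01,
                        intercept = 3, shape = "decline",
                        residual_sd = 0.1)
  expect_equal(trajectory_value(sp, 10), 2.9)
  # powers (0,1,1) at age 1: ln terms vanish, only the linear one remains
  sp2 <- trajectory_spec("r", powers = c(0, 1, 1),
                         coefficients = c(-0.2, -0.004, 0.0004),
                         intercept = 3.2, shape = "decline",
                         residual_sd = 0.1)
  expect_equal(trajectory_value(sp2, 1), 3.2 - 0.004)
  expect_error(trajectory_value(sp, 0), "positive")
})

test_that("inverse-U specs place the derivative flip at the vertex", {
  c1 <- 0.006
  sp <- trajectory_spec("r", powers = c(1, 2),
                        coefficients = c(c1, -c1 / (2 * 65)),
                        intercept = 3, shape = "inverse_U",
                        residual_sd = 0.1)
  grid <- seq(3, 90, by = 0.1)
  d <- diff(trajectory_value(sp, grid))
  flip_age <- grid[max(which(d > 0))]
  expect_lt(abs(flip_age - 65), 0.25)   # finite-difference vertex
  # declared shape must match the realized sign pattern
  expect_error(
    trajectory_spec("r", powers = c(1, 2),
                    coefficients = c(c1, -c1 / (2 * 65)),
                    intercept = 3, shape = "decline", residual_sd = 0.1),
    "shape")
})

test_that("generation is deterministic and respects the noise-free limit", {
  sp <- trajectory_spec("r1", powers = 1, coefficients = -0.01,
                        intercept = 3, shape = "decline",
                        residual_sd = 1e-12)
  cfg <- generator_config(list(site_spec("A", n_subjects = 50)), list(sp),
                          seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(g1$cohort), as.data.frame(g2$cohort))
  expect_equal(g1$cohort$r1,
               3 - 0.01 * g1$cohort$age +
                 0.01 * 0 * (g1$cohort$sex == "male"),
               tolerance = 1e-9)
  expect_error(generator_config(list(), list(sp)), "non-empty")
})

test_that("site location shifts are recovered by large-sample means", {
  sp <- trajectory_spec("r1", powers = 1, coefficients = -0.01,
                        intercept = 3, shape = "decline", residual_sd = 0.15)
  cfg <- generator_config(
    list(site_spec("A", gamma = 0, n_subjects = 5000),
         site_spec("B", gamma = 0.3, n_subjects = 5000)),
    list(sp), seed = 11)
  g <- generate_cohort(cfg)$cohort
  mns <- tapply(g$r1, g$site_id, mean)
  # ages are iid across sites, so the mean difference estimates gamma
  expect_lt(abs((mns[["B"]] - mns[["A"]]) - 0.3), 0.01)
})

test_that("residual scale factors and sex balance match the config", {
  sp <- trajectory_spec("r1", powers = 1, coefficients = 0,
                        intercept = 3, shape = "decline", residual_sd = 0.2)
  cfg <- generator_config(
    list(site_spec("A", delta = 1, n_subjects = 5000, age_low = 30,
                   age_high = 31),
         site_spec("B", delta = 1.5, n_subjects = 5000, age_low = 30,
                   age_high = 31)),
    list(sp), female_fraction = 0.52, seed = 3)
  g <- generate_cohort(cfg)$cohort
  sds <- tapply(g$r1, g$site_id, sd)
  expect_lt(abs(sds[["A"]] / 0.2 - 1), 0.05)
  expect_lt(abs(sds[["B"]] / 0.3 - 1), 0.05)
  ff <- mean(g$sex == "female")
  se <- sqrt(0.52 * 0.48 / nrow(g))
  expect_lt(abs(ff - 0.52), 3 * se)
})

test_that("the preset mirrors the published cohort structure", {
  cfg <- enigma_like_config(scale = 0.05, seed = 2)
  expect_length(cfg$sites, 83)
  expect_length(cfg$trajectories, 68)
  shapes <- vapply(cfg$trajectories, function(s) s$shape, character(1))
  regions <- vapply(cfg$trajectories, function(s) s$region, character(1))
  expect_equal(sum(shapes == "inverse_U"), 4)   # entorhinal + temporopolar
  expect_equal(sum(shapes == "attenuated_U"), 4)  # anterior cingulate
  expect_true(all(grepl("entorhinal|temporalpole",
                        regions[shapes == "inverse_U"])))
  expect_true(all(grepl("anteriorcingulate",
                        regions[shapes == "attenuated_U"])))
  g <- generate_cohort(cfg)$cohort
  expect_length(cohort_regions(g), 68)
  expect_equal(length(unique(g$site_id)), 83)
  expect_true(min(g$age) >= 3 && max(g$age) <= 90)
  expect_lt(abs(mean(g$sex == "female") - 0.52), 0.05)
})

test_that("generation order does not leak across site RNG streams", {
  sp <- trajectory_spec("r1", powers = 1, coefficients = -0.01,
                        intercept = 3, shape = "decline", residual_sd = 0.1)
  s1 <- site_spec("A", n_subjects = 20)
  s2 <- site_spec("B", n_subjects = 20)
  g12 <- generate_cohort(generator_config(list(s1, s2), list(sp), seed = 9))
  g21 <- generate_cohort(generator_config(list(s2, s1), list(sp), seed = 9))
  a12 <- g12$cohort[g12$cohort$site_id == "A", ]
  a21 <- g21$cohort[g21$cohort$site_id == "A", ]
  rownames(a12) <- rownames(a21) <- NULL
  expect_equal(as.data.frame(a12), as.data.frame(a21))
})
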