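# Small in-code cohort builders used across the suite.

# minimal multi-site cohort with a handful of regions and linear-ish truth
mk_cohort <- function(n_per_site = 200, sites = c("A", "B"),
                      gammas = rep(0, length(sites)),
                      deltas = rep(1, length(sites)),
                      seed = 1, age_range = c(5, 85),
                      sex_effect = 0.05) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_along(sites), function(i) {
    age <- stats::runif(n_per_site, age_range[1], age_range[2])
    sex <- sample(c("male", "female"), n_per_site, TRUE)
    data.frame(
      subject_id = paste0(sites[i], "_", seq_len(n_per_site)),
      site_id = sites[i], sex = sex, age = age,
      r1 = 3 - 0.01 * age + gammas[i] + deltas[i] * rnorm(n_per_site, sd = 0.15),
      r2 = 2.5 - 0.005 * age + sex_effect * (sex == "female") +
        gammas[i] + deltas[i] * rnorm(n_per_site, sd = 0.1),
      r3 = 2.8 - 0.008 * age + 0.5 * gammas[i] +
        deltas[i] * rnorm(n_per_site, sd = 0.12),
      stringsAsFactors = FALSE)
  }))
  structure(df, regions = c("r1", "r2", "r3"), age_bounds = c(3, 90),
            class = c("cohort_table", "data.frame"))
}

# cohort whose single region follows an exact FP mean plus Gaussian noise
mk_fp_cohort <- function(n = 5000, powers = 1, coefs = -0.01,
                         intercept = 3, noise_sd = 0.15, seed = 1,
                         n_sites = 5, age_range = c(3, 90),
                         site_gamma_sd = 0, sex_effect = 0.02) {
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- sample(c("male", "female"), n, TRUE)
  site <- sample(paste0("S", seq_len(n_sites)), n, TRUE)
  gam <- stats::rnorm(n_sites, 0, site_gamma_sd)
  names(gam) <- paste0("S", seq_len(n_sites))
  mu <- intercept + drop(fp_basis(age, powers) %*% coefs) +
    sex_effect * (sex == "female")
  y <- mu + gam[site] + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
  df <- data.frame(subject_id = paste0("s", seq_len(n)), site_id = site,
                   sex = sex, age = age, y = y, stringsAsFactors = FALSE)
  structure(df, regions = "y", age_bounds = c(3, 90),
            class = c("cohort_table", "data.frame"))
}

# well-formed 68-region data frame for io tests (3 subjects by default)
mk_io_frame <- function(n = 3, registry = region_registry(), seed = 99) {
  set.seed(seed)
  df <- data.frame(subject_id = paste0("sub", seq_len(n)),
                   site_id = "X", sex = rep(c("F", "M"), length.out = n),
                   age = seq(10, 60, length.out = n),
                   stringsAsFactors = FALSE)
  vals <- matrix(round(runif(n * 68, 1.5, 3.5), 3), nrow = n)
  colnames(vals) <- registry$label
  cbind(df, as.data.frame(vals, check.names = FALSE))
}
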