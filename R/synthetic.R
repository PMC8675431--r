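# Multi-site synthetic lifespan cohorts with known ground truth.
# Trajectory means reuse the FP basis so downstream model recovery can be
# checked against the generating coefficients.

# plausible region-level mean thickness (mm) and surface area (mm^2),
# used to anchor the synthetic trajectories at age 30
.dk_base_thickness <- c(
  bankssts = 2.60, caudalanteriorcingulate = 2.80, caudalmiddlefrontal = 2.60,
  cuneus = 1.90, entorhinal = 3.40, frontalpole = 2.90, fusiform = 2.75,
  inferiorparietal = 2.50, inferiortemporal = 2.80, insula = 3.10,
  isthmuscingulate = 2.50, lateraloccipital = 2.20,
  lateralorbitofrontal = 2.70, lingual = 2.00, medialorbitofrontal = 2.50,
  middletemporal = 2.90, paracentral = 2.45, parahippocampal = 2.80,
  parsopercularis = 2.65, parsorbitalis = 2.70, parstriangularis = 2.55,
  pericalcarine = 1.65, postcentral = 2.10, posteriorcingulate = 2.50,
  precentral = 2.60, precuneus = 2.40, rostralanteriorcingulate = 2.90,
  rostralmiddlefrontal = 2.45, superiorfrontal = 2.70,
  superiorparietal = 2.25, superiortemporal = 2.85, supramarginal = 2.60,
  temporalpole = 3.70, transversetemporal = 2.40)

.dk_mean_area <- c(
  bankssts = 1000, caudalanteriorcingulate = 700, caudalmiddlefrontal = 2200,
  cuneus = 1500, entorhinal = 400, frontalpole = 250, fusiform = 3500,
  inferiorparietal = 5000, inferiortemporal = 3600, insula = 2400,
  isthmuscingulate = 1000, lateraloccipital = 5000,
  lateralorbitofrontal = 2700, lingual = 3000, medialorbitofrontal = 2000,
  middletemporal = 3500, paracentral = 1500, parahippocampal = 750,
  parsopercularis = 1700, parsorbitalis = 700, parstriangularis = 1500,
  pericalcarine = 1500, postcentral = 4500, posteriorcingulate = 1200,
  precentral = 5000, precuneus = 4000, rostralanteriorcingulate = 800,
  rostralmiddlefrontal = 5500, superiorfrontal = 7000,
  superiorparietal = 5500, superiortemporal = 4000, supramarginal = 3800,
  temporalpole = 450, transversetemporal = 500)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic 31-bit stream seed for a site, independent of iteration order
.site_seed <- function(master_seed, site_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(site_id)))
    h <- (h * 31 + ch) %% 1000003
  as.integer((h * 2011 + as.numeric(master_seed)) %% 2147483647)
}

#' Ground-truth trajectory specification for one region
#'
#' Defines the generating mean curve of a region as an FP basis expansion
#' plus an additive sex offset, with Gaussian residual scatter.
#'
#' @param region Region column label.
#' @param powers FP power multiset of the mean curve.
#' @param coefficients Coefficients of the basis columns (mm per basis unit).
#' @param intercept Intercept (mm).
#' @param sex_offset mm added for males (default 0).
#' @param shape One of `"decline"`, `"inverse_U"`, `"attenuated_U"`; checked
#'   against the sign pattern of the curve's derivative on [3, 90].
#' @param residual_sd Residual SD in mm (> 0), default 0.15.
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(region, powers, coefficients, intercept,
                            sex_offset = 0,
                            shape = c("decline", "inverse_U", "attenuated_U"),
                            residual_sd = 0.15) {
  shape <- match.arg(shape)
  powers <- .canonical_powers(powers)
  stopifnot(length(coefficients) == length(powers), residual_sd > 0)
  spec <- structure(list(region = region, powers = powers,
                         coefficients = as.numeric(coefficients),
                         intercept = as.numeric(intercept),
                         sex_offset = as.numeric(sex_offset),
                         shape = shape, residual_sd = residual_sd),
                    class = "trajectory_spec")
  grid <- seq(3, 90, by = 0.25)
  vals <- trajectory_value(spec, grid, sex = "female")
  if (any(vals <= 0))
    stop("trajectory for ", region, " is not positive over [3, 90]")
  d <- diff(vals)
  sgn <- sign(d[abs(d) > 1e-12])
  flips <- sum(diff(sgn) != 0)
  ok <- switch(shape,
               decline = all(sgn <= 0),
               inverse_U = flips == 1 && sgn[1] > 0 &&
                 sgn[length(sgn)] < 0,
               attenuated_U = flips == 1 && sgn[1] < 0 &&
                 sgn[length(sgn)] > 0)
  if (!ok)
    stop("derivative sign pattern of ", region,
         " does not match declared shape '", shape, "'")
  spec
}

#' Evaluate a ground-truth trajectory
#'
#' @param spec A [trajectory_spec()].
#' @param age Positive ages in years (vectorized).
#' @param sex `"male"` or `"female"` (scalar or vector).
#' @return Mean thickness in mm.
#' @export
trajectory_value <- function(spec, age, sex = "female") {
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  b <- fp_basis(age, spec$powers)
  drop(spec$intercept + b %*% spec$coefficients +
         spec$sex_offset * (sex == "male"))
}

#' Site effect specification
#'
#' @param site_id Site identifier.
#' @param gamma Additive location shift in mm.
#' @param delta Multiplicative residual-scale factor (> 0).
#' @param n_subjects Number of subjects to simulate.
#' @param age_low,age_high Site age range in years, within [3, 90].
#' @param female_fraction Site-specific female fraction, or `NA` to use the
#'   cohort-level default.
#' @return Object of class `site_spec`.
#' @export
site_spec <- function(site_id, gamma = 0, delta = 1, n_subjects = 100,
                      age_low = 3, age_high = 90, female_fraction = NA) {
  stopifnot(delta > 0, n_subjects >= 1,
            age_low >= 3, age_high <= 90, age_low < age_high)
  structure(list(site_id = as.character(site_id), gamma = gamma,
                 delta = delta, n_subjects = as.integer(n_subjects),
                 age_low = age_low, age_high = age_high,
                 female_fraction = female_fraction),
            class = "site_spec")
}

#' Generator configuration
#'
#' @param sites List of [site_spec()]s (non-empty).
#' @param trajectories List of [trajectory_spec()]s, one per region.
#' @param female_fraction Default female fraction, in (0, 1); default 0.52.
#' @param seed Master integer seed; fully determines the generated cohort.
#' @param emit_areas If `TRUE`, also emit per-subject surface-area columns.
#' @param registry Region registry the trajectory regions must cover.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(sites, trajectories, female_fraction = 0.52,
                             seed = 1, emit_areas = FALSE,
                             registry = NULL) {
  if (!length(sites)) stop("site list must be non-empty")
  stopifnot(female_fraction > 0, female_fraction < 1)
  regions <- vapply(trajectories, function(s) s$region, character(1))
  if (anyDuplicated(regions)) stop("duplicate trajectory regions")
  structure(list(sites = sites, trajectories = trajectories,
                 female_fraction = female_fraction, seed = as.integer(seed),
                 emit_areas = emit_areas, registry = registry,
                 regions = regions),
            class = "generator_config")
}

#' Generate a synthetic multi-site cohort
#'
#' Each subject's regional value is `trajectory mean + gamma_site +
#' delta_site * e`, with `e ~ Normal(0, residual_sd)`. One RNG stream per
#' site is derived from the master seed and the site id, so the output is
#' reproducible independently of site order.
#'
#' @param config A [generator_config()].
#' @return List with elements `cohort` (a `cohort_table`) and `truth`
#'   (the generating site and trajectory specifications).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  regions <- config$regions
  tspecs <- config$trajectories
  site_frames <- lapply(config$sites, function(st) {
    n <- st$n_subjects
    ff <- if (is.na(st$female_fraction)) config$female_fraction
          else st$female_fraction
    .with_seed(.site_seed(config$seed, st$site_id), {
      age <- stats::runif(n, st$age_low, st$age_high)
      sex <- ifelse(stats::runif(n) < ff, "female", "male")
      noise <- matrix(stats::rnorm(n * length(regions)), nrow = n)
      vals <- matrix(NA_real_, n, length(regions))
      for (j in seq_along(regions)) {
        mu <- trajectory_value(tspecs[[j]], age, sex)
        vals[, j] <- mu + st$gamma +
          st$delta * tspecs[[j]]$residual_sd * noise[, j]
      }
      colnames(vals) <- regions
      df <- data.frame(subject_id = sprintf("%s_%04d", st$site_id, seq_len(n)),
                       site_id = st$site_id, sex = sex, age = age,
                       stringsAsFactors = FALSE, check.names = FALSE)
      df <- cbind(df, as.data.frame(vals, check.names = FALSE))
      if (isTRUE(config$emit_areas)) {
        areg <- region_registry("surfavg")
        amean <- .dk_mean_area[areg$region]
        areas <- matrix(rep(amean, each = n), nrow = n) *
          exp(matrix(stats::rnorm(n * 68, sd = 0.1), nrow = n))
        colnames(areas) <- areg$label
        df <- cbind(df, as.data.frame(areas, check.names = FALSE))
      }
      df
    })
  })
  df <- do.call(rbind, site_frames)
  registry <- config$registry
  if (length(regions) != 68) {
    # partial-region configs keep a bespoke registry for testing speed
    registry <- structure(
      data.frame(label = regions, hemisphere = NA_character_,
                 region = regions, stringsAsFactors = FALSE),
      class = c("region_registry", "data.frame"))
    cohort <- df
    cohort$sex <- .parse_sex(cohort$sex)
    cohort <- structure(cohort, regions = regions, registry = registry,
                        area_regions = character(0),
                        age_bounds = c(3, 90),
                        exclusions = c(bad_sex = 0L, bad_age = 0L,
                                       incomplete = 0L, duplicate_id = 0L),
                        class = c("cohort_table", "data.frame"))
  } else {
    if (is.null(registry)) registry <- region_registry(labels = regions)
    cohort <- as_cohort_table(df, registry = registry)
  }
  list(cohort = cohort,
       truth = list(sites = config$sites, trajectories = tspecs,
                    config = config))
}

#' Ground-truth trajectory set emulating the pooled lifespan data
#'
#' Region shapes follow the qualitative lifespan pattern: monotone decline
#' for most regions (steeper before the third decade), an inverse-U peaking
#' in late life for entorhinal and temporopolar cortex, and a shallow
#' (attenuated) U for the anterior cingulate.
#'
#' @param residual_sd Residual SD in mm, default 0.15.
#' @param sex_offset mm added for males, default 0.01.
#' @param registry Region registry (68 labels).
#' @return List of 68 [trajectory_spec()]s.
#' @export
enigma_like_trajectories <- function(residual_sd = 0.15, sex_offset = 0.01,
                                     registry = region_registry()) {
  inverse_u <- c("entorhinal", "temporalpole")
  atten_u <- c("rostralanteriorcingulate", "caudalanteriorcingulate")
  lapply(seq_len(nrow(registry)), function(i) {
    rg <- registry$region[i]
    base <- .dk_base_thickness[[rg]]
    if (rg %in% inverse_u) {
      c1 <- 0.006; c2 <- -c1 / (2 * 65)   # vertex at 65 y
      trajectory_spec(registry$label[i], c(1, 2), c(c1, c2),
                      intercept = base - (c1 * 30 + c2 * 900),
                      sex_offset = sex_offset, shape = "inverse_U",
                      residual_sd = residual_sd)
    } else if (rg %in% atten_u) {
      c1 <- -0.0022; c2 <- c1 / (-2 * 55)  # shallow minimum at 55 y
      trajectory_spec(registry$label[i], c(1, 2), c(c1, c2),
                      intercept = base - (c1 * 30 + c2 * 900),
                      sex_offset = sex_offset, shape = "attenuated_U",
                      residual_sd = residual_sd)
    } else {
      f <- 0.85 + 0.3 * ((i * 7) %% 34) / 33  # deterministic region variation
      co <- c(-0.15 * f, -0.003 * f)          # ln + linear decline
      trajectory_spec(registry$label[i], c(0, 1), co,
                      intercept = base - (co[1] * log(30) + co[2] * 30),
                      sex_offset = sex_offset, shape = "decline",
                      residual_sd = residual_sd)
    }
  })
}

#' Preset generator configuration mirroring the pooled 83-site study
#'
#' Sites are taken from [site_characteristics()]: per-site sample size
#' (optionally scaled down), age range (clamped to [3, 90]) and sex split.
#' Site location shifts are drawn once per preset as gamma ~ N(0, `gamma_sd`)
#' and scale factors as delta ~ exp(N(0, `delta_sdlog`)), from an RNG stream
#' derived from the master seed.
#'
#' @param scale Multiplier on per-site N (e.g. 0.1 for a 10% cohort);
#'   each site keeps at least 2 subjects.
#' @param seed Master seed.
#' @param residual_sd Residual SD in mm, default 0.15.
#' @param sex_offset mm added for males, default 0.01.
#' @param gamma_sd SD of site location shifts (mm), default 0.1.
#' @param delta_sdlog SD of log site scale factors, default 0.1.
#' @param emit_areas Emit surface-area columns too.
#' @return A [generator_config()].
#' @export
enigma_like_config <- function(scale = 1, seed = 1, residual_sd = 0.15,
                               sex_offset = 0.01, gamma_sd = 0.1,
                               delta_sdlog = 0.1, emit_areas = FALSE) {
  tab <- site_characteristics()
  k <- nrow(tab)
  eff <- .with_seed(.site_seed(seed, "site-effects"), {
    list(gamma = stats::rnorm(k, 0, gamma_sd),
         delta = exp(stats::rnorm(k, 0, delta_sdlog)))
  })
  sites <- lapply(seq_len(k), function(i) {
    site_spec(tab$sample[i], gamma = eff$gamma[i], delta = eff$delta[i],
              n_subjects = max(2L, round(scale * tab$n_total[i])),
              age_low = max(3, tab$age_min[i]),
              age_high = min(90, tab$age_max[i]),
              female_fraction = tab$n_female[i] / tab$n_total[i])
  })
  # all-male sites would make a Bernoulli(0) draw; nudge inside (0,1)
  for (i in seq_along(sites))
    if (sites[[i]]$female_fraction <= 0)
      sites[[i]]$female_fraction <- 1e-9
  generator_config(sites,
                   enigma_like_trajectories(residual_sd, sex_offset),
                   female_fraction = 0.52, seed = seed,
                   emit_areas = emit_areas)
}
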