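# Fractional-polynomial regression: centered OLS fits with cluster-robust
# covariance, exhaustive 494-model scans and ascending closed-test selection.

# centered design for one region: FP basis columns + female indicator
.fp_design <- function(table, region, powers, sex_covariate = TRUE) {
  y <- table[[region]]
  if (is.null(y)) stop("region '", region, "' not present in cohort table")
  X <- fp_basis(table$age, powers)
  if (sex_covariate) {
    X <- cbind(X, `sex(female)` = as.numeric(table$sex == "female"))
  }
  list(y = y, X = X)
}

#' Fit a fractional-polynomial model for one region
#'
#' Ordinary least squares of regional thickness on the FP basis of age plus
#' a female indicator. The response and every design column are mean-centered
#' per region, so the fitted intercept is exactly zero; fitted curves are
#' reported by re-adding the stored means. The coefficient covariance is
#' additionally computed clustered by site (CR1 small-sample adjustment) to
#' reflect residual scanner dependence.
#'
#' @param table A `cohort_table`.
#' @param region Region column name.
#' @param powers FP power multiset.
#' @param cluster_by Column to cluster robust standard errors by
#'   (default `"site_id"`).
#' @param sex_covariate Include the female indicator (default `TRUE`).
#' @return Object of class `fp_fit` with coefficients, RSS, residuals,
#'   naive and cluster-robust covariance, and R-squared.
#' @export
fit_fp <- function(table, region, powers, cluster_by = "site_id",
                   sex_covariate = TRUE) {
  d <- .fp_design(table, region, powers, sex_covariate)
  n <- length(d$y)
  k <- ncol(d$X)
  if (n <= k + 2) stop("too few rows (", n, ") for ", k, " design columns")
  xbar <- colMeans(d$X)
  ybar <- mean(d$y)
  Xc <- sweep(d$X, 2, xbar)
  yc <- d$y - ybar
  qrX <- qr(Xc)
  if (qrX$rank < k) {
    bad <- colnames(d$X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient FP design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(yc ~ 0 + Xc)
  beta <- stats::coef(fit)
  names(beta) <- colnames(d$X)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum(yc^2)
  # naive covariance with the conventional intercept-inclusive df (n - k - 1)
  XtXinv <- chol2inv(qr.R(qrX))
  vc_naive <- XtXinv * rss / (n - k - 1)
  dimnames(vc_naive) <- list(names(beta), names(beta))
  vc_robust <- if (!is.null(cluster_by) && cluster_by %in% names(table) &&
                   length(unique(table[[cluster_by]])) > 1) {
    # bread() warns about "essentially perfect fit" on noiseless designs
    v <- withCallingHandlers(
      sandwich::vcovCL(fit, cluster = table[[cluster_by]],
                       type = "HC1", cadjust = TRUE),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    dimnames(v) <- list(names(beta), names(beta))
    v
  } else vc_naive
  structure(list(region = region, powers = .canonical_powers(powers),
                 degree = length(powers),
                 coefficients = beta, center = list(x = xbar, y = ybar),
                 residuals = as.numeric(res), rss = rss, tss = tss,
                 n = n, df_model = k,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 vcov_naive = vc_naive, vcov_robust = vc_robust,
                 sex_covariate = sex_covariate,
                 age_range = range(table$age)),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit> region ", x$region, ", powers ", fp_powers_label(x$powers),
      ", n = ", x$n, ", R^2 = ", round(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Fitted mean thickness curve of an FP fit
#'
#' Evaluates the fitted population mean curve (sex indicator held at its
#' sample mean, which the centering removes) at arbitrary ages.
#'
#' @param fit An `fp_fit`.
#' @param ages Ages in years.
#' @return Numeric vector of fitted thickness (mm).
#' @export
fp_curve <- function(fit, ages) {
  B <- fp_basis(ages, fit$powers)
  nb <- ncol(B)
  beta <- fit$coefficients[seq_len(nb)]
  drop(fit$center$y + sweep(B, 2, fit$center$x[seq_len(nb)]) %*% beta)
}

#' Partial F-test between nested FP fits
#'
#' F = ((RSS_s - RSS_b) / (df_b - df_s)) / (RSS_b / (n - df_b - 1)).
#' Within the FP family every lower-degree model is nested in a model of the
#' next degree, so per-degree best fits are compared with this statistic.
#'
#' @param fit_small,fit_big `fp_fit` objects on the same rows with
#'   `df_model` strictly increasing.
#' @return List with elements `F`, `df1`, `df2` and `p`.
#' @export
partial_f_test <- function(fit_small, fit_big) {
  if (fit_small$n != fit_big$n)
    stop("fits must use the same rows (unequal n)")
  df1 <- fit_big$df_model - fit_small$df_model
  if (df1 <= 0)
    stop("fit_small must be nested in fit_big (fewer design columns)")
  df2 <- fit_big$n - fit_big$df_model - 1
  f <- max(0, (fit_small$rss - fit_big$rss) / df1) / (fit_big$rss / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Variance explained by an FP fit
#'
#' @param fit An `fp_fit`.
#' @return R-squared on the analysis sample.
#' @export
variance_explained <- function(fit) {
  if (!is.finite(fit$tss) || fit$tss <= 0)
    stop("response has zero total variance")
  1 - fit$rss / fit$tss
}

#' Age at maximum fitted thickness
#'
#' Argmax of the fitted mean curve on a uniform age grid; ties are broken
#' toward the youngest age.
#'
#' @param fit An `fp_fit`.
#' @param age_range Two-element range (default the fit's observed range).
#' @param grid_step Grid resolution in years, default 0.1.
#' @return Age in years.
#' @export
age_at_max <- function(fit, age_range = NULL, grid_step = 0.1) {
  if (is.null(age_range)) age_range <- fit$age_range
  if (age_range[1] <= 0) stop("age range must be positive")
  grid <- seq(age_range[1], age_range[2], by = grid_step)
  vals <- fp_curve(fit, grid)
  grid[which.max(vals)]  # which.max returns the first (youngest) maximum
}

#' Classify the shape of a fitted trajectory
#'
#' Labels the fitted mean curve on an age grid by the sign pattern of its
#' first differences: monotone non-increasing is `"decline"`, rise-then-fall
#' `"inverse_U"`, fall-then-rise `"attenuated_U"`, monotone increase
#' `"incline"`, anything else `"other"`.
#'
#' @param fit An `fp_fit`.
#' @param age_range Two-element range, default `c(3, 90)`.
#' @param grid_step Grid resolution in years, default 0.25.
#' @param tol Slope magnitudes below `tol` (mm/step) count as flat.
#' @return Character scalar.
#' @export
classify_trajectory_shape <- function(fit, age_range = c(3, 90),
                                      grid_step = 0.25, tol = 1e-6) {
  grid <- seq(age_range[1], age_range[2], by = grid_step)
  d <- diff(fp_curve(fit, grid))
  sgn <- sign(d[abs(d) > tol])
  if (!length(sgn)) return("decline")  # flat curve: no age-related change
  flips <- sum(diff(sgn) != 0)
  if (flips == 0) {
    if (sgn[1] < 0) "decline" else "incline"
  } else if (flips == 1) {
    if (sgn[1] > 0) "inverse_U" else "attenuated_U"
  } else "other"
}

# ---- fast exhaustive scan -------------------------------------------------

# distinct basis terms over all candidate models: age^p * ln(age)^k
.fp_term_key <- function(p, k) paste0(p, "|", k)

.fp_model_keys <- function(powers) {
  tab <- table(powers)
  unlist(lapply(names(tab), function(ps) {
    p <- as.numeric(ps)
    .fp_term_key(p, seq_len(tab[[ps]]) - 1L)
  }), use.names = FALSE)
}

.fp_term_matrix <- function(ages, powers, max_degree) {
  la <- log(ages)
  keys <- character(0)
  cols <- list()
  for (p in sort(unique(powers))) {
    base <- if (p == 0) la else ages^p
    cur <- base
    for (k in 0:(max_degree - 1L)) {
      if (k > 0) cur <- cur * la
      keys <- c(keys, .fp_term_key(p, k))
      cols[[length(cols) + 1L]] <- cur
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- keys
  out
}

# RSS of every candidate model via precomputed centered cross-products
.fp_scan <- function(ages, y, sex_female, max_degree = 4,
                     powers = fp_power_set()) {
  models <- enumerate_fp_powers(max_degree, powers)
  TM <- .fp_term_matrix(ages, powers, max_degree)
  X <- cbind(TM, `sex(female)` = sex_female)
  X <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  G <- crossprod(X)
  Xy <- crossprod(X, yc)
  yy <- sum(yc^2)
  scl <- sqrt(diag(G))
  scl[scl < 1e-300] <- 1
  sex_idx <- ncol(X)
  rss <- vapply(models, function(pw) {
    idx <- c(match(.fp_model_keys(pw), colnames(TM)), sex_idx)
    Gs <- G[idx, idx] / tcrossprod(scl[idx])
    b <- tryCatch(solve(Gs, Xy[idx] / scl[idx]), error = function(e) NULL)
    if (is.null(b) || kappa(Gs, exact = FALSE) > 1e12) return(NA_real_)
    max(0, yy - sum(b * Xy[idx] / scl[idx]))
  }, numeric(1))
  data.frame(model = I(models),
             degree = lengths(models),
             label = vapply(models, fp_powers_label, character(1)),
             rss = rss, stringsAsFactors = FALSE)
}

#' Exhaustive FP model selection for one region
#'
#' Enumerates the full candidate family (494 models for the standard power
#' set with degree up to 4), ranks models within each degree by residual sum
#' of squares, then runs the ascending closed test: degree d+1 replaces
#' degree d only if the partial F-test of the per-degree best fits has
#' p < `alpha`. The default `alpha = 0.01` is the permutation-calibrated
#' threshold guarding against over-fitting.
#'
#' @param table A `cohort_table`.
#' @param region Region column name.
#' @param alpha Significance level of the closed test, default 0.01.
#' @param max_degree Maximum FP degree, default 4.
#' @param powers Candidate power set.
#' @param cluster_by Cluster column for robust covariance of the refits.
#' @param descending If `TRUE`, use the descending variant instead: start at
#'   `max_degree` and step down while the higher degree is *not* a
#'   significant improvement.
#' @return Object of class `fp_selection`: per-degree best fits, the
#'   comparison table (F, p per adjacent-degree test), the selected fit,
#'   its age at maximum thickness and variance explained.
#' @export
select_fp_model <- function(table, region, alpha = 0.01, max_degree = 4,
                            powers = fp_power_set(), cluster_by = "site_id",
                            descending = FALSE) {
  scan <- .fp_scan(table$age, table[[region]],
                   as.numeric(table$sex == "female"),
                   max_degree = max_degree, powers = powers)
  best <- lapply(seq_len(max_degree), function(d) {
    sub <- scan[scan$degree == d & is.finite(scan$rss), , drop = FALSE]
    if (!nrow(sub)) stop("no estimable degree-", d, " model")
    # min-RSS winner; canonical power order breaks exact ties
    sub$model[[which.min(sub$rss)]]
  })
  fits <- lapply(best, function(pw)
    fit_fp(table, region, pw, cluster_by = cluster_by))
  comparisons <- do.call(rbind, lapply(seq_len(max_degree - 1), function(d) {
    ft <- partial_f_test(fits[[d]], fits[[d + 1]])
    data.frame(degree_small = d, degree_big = d + 1,
               F = ft$F, df1 = ft$df1, df2 = ft$df2, p = ft$p)
  }))
  if (descending) {
    accepted <- 1L
    for (d in rev(seq_len(max_degree - 1L))) {
      if (comparisons$p[d] < alpha) { accepted <- d + 1L; break }
    }
  } else {
    accepted <- 1L
    for (d in seq_len(max_degree - 1L)) {
      if (comparisons$p[d] < alpha) accepted <- d + 1L else break
    }
  }
  sel <- fits[[accepted]]
  # the trajectory summary spans the study age range, not the possibly
  # QC-narrowed observed range
  bounds <- attr(table, "age_bounds")
  if (is.null(bounds)) bounds <- sel$age_range
  structure(list(region = region, best_by_degree = fits,
                 comparisons = comparisons, alpha = alpha,
                 selected = sel, selected_powers = sel$powers,
                 selected_degree = accepted,
                 age_at_max = age_at_max(sel, age_range = bounds),
                 variance_explained = variance_explained(sel),
                 n_candidates = nrow(scan)),
            class = "fp_selection")
}

#' @export
print.fp_selection <- function(x, ...) {
  cat("<fp_selection> region ", x$region, ": powers ",
      fp_powers_label(x$selected_powers), " (degree ", x$selected_degree,
      "), R^2 = ", round(x$variance_explained, 4),
      ", age at max = ", round(x$age_at_max, 1), " y\n", sep = "")
  invisible(x)
}

#' Permutation check of the selection alpha
#'
#' Permutes ages across subjects within site (destroying any age-thickness
#' association while keeping the site structure), reruns the closed-test
#' comparisons, and reports the distribution of the minimal adjacent-degree
#' p-value under this null together with the fraction of permutations in
#' which a degree > 1 model would be accepted at the nominal alpha.
#'
#' @param table A `cohort_table`.
#' @param region Region column name.
#' @param B Number of permutations, >= 100.
#' @param nominal Nominal alpha of the closed test, default 0.01.
#' @param seed Optional integer seed making the permutations reproducible.
#' @param max_degree,powers Candidate family, as in [select_fp_model()].
#' @return List with `p_min` (B minimal null p-values), their `quantiles`,
#'   and `overfit_fraction`.
#' @export
permutation_alpha <- function(table, region, B = 200, nominal = 0.01,
                              seed = NULL, max_degree = 4,
                              powers = fp_power_set()) {
  if (B < 100) stop("B must be at least 100")
  run <- function() {
    p_min <- numeric(B)
    accept <- logical(B)
    for (b in seq_len(B)) {
      perm <- stats::ave(seq_len(nrow(table)), table$site_id,
                         FUN = function(i)
                           if (length(i) == 1L) i else sample(i))
      tb <- table
      tb$age <- table$age[perm]
      sel <- select_fp_model(tb, region, alpha = nominal,
                             max_degree = max_degree, powers = powers,
                             cluster_by = NULL)
      p_min[b] <- min(sel$comparisons$p)
      accept[b] <- sel$selected_degree > 1L
    }
    list(p_min = p_min,
         quantiles = stats::quantile(p_min, c(0.01, 0.05, 0.1, 0.5)),
         overfit_fraction = mean(accept))
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}
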