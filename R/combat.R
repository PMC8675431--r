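# Empirical-Bayes location/scale site harmonization (ComBat) with an
# explicit fit/apply split so a fitted model can harmonize new rows from
# known sites.

#' Covariate design description for harmonization
#'
#' The biological covariates preserved by harmonization: a female indicator
#' and a flexible FP age basis (default powers (0, 1, 1), i.e. ln a, a,
#' a ln a) so nonlinear age signal is treated as biology, not scanner noise.
#'
#' @param age_powers FP power multiset for the age basis, or `NULL` for no
#'   age adjustment.
#' @param sex Include the female indicator.
#' @return Object of class `combat_design`.
#' @export
combat_design <- function(age_powers = c(0, 1, 1), sex = TRUE) {
  structure(list(age_powers = age_powers, sex = sex),
            class = "combat_design")
}

.combat_covariates <- function(design, table) {
  parts <- list()
  if (!is.null(design$age_powers))
    parts$age <- fp_basis(table$age, design$age_powers)
  if (isTRUE(design$sex))
    parts$sex <- cbind(`sex(female)` = as.numeric(table$sex == "female"))
  if (!length(parts)) return(NULL)
  do.call(cbind, parts)
}

#' Fit an empirical-Bayes site-harmonization model
#'
#' Location/scale harmonization: per region, thickness is modelled as
#' grand mean + covariate effects + additive site shift gamma + site-scaled
#' residual delta * e. Regions are standardized by the pooled residual
#' scale, per-site location/scale estimates are computed, and (if `eb`)
#' shrunk via parametric empirical-Bayes priors - normal for location,
#' inverse-gamma for scale, hyperparameters by method of moments - solved by
#' the standard iterative conditional-means scheme.
#'
#' @param table A `cohort_table`.
#' @param design A [combat_design()] describing covariates to preserve.
#' @param eb Apply empirical-Bayes shrinkage (default `TRUE`).
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   posterior estimates, default 1e-6.
#' @param max_iter Maximum iterations of the EB scheme, default 500.
#' @return Object of class `combat_model`.
#' @export
fit_combat <- function(table, design = combat_design(), eb = TRUE,
                       tol = 1e-6, max_iter = 500) {
  regions <- cohort_regions(table)
  Y <- as.matrix(table[, regions, drop = FALSE])
  site <- factor(table$site_id)
  sites <- levels(site)
  n_i <- as.integer(table(site))
  if (any(n_i < 2)) stop("every site needs at least 2 subjects; offending: ",
                         paste(sites[n_i < 2], collapse = ", "))
  n <- nrow(Y)
  Bmat <- vapply(sites, function(s) as.numeric(site == s),
                 numeric(n))  # one-hot site design, valid for 1 site too
  C <- .combat_covariates(design, table)
  X <- if (is.null(C)) Bmat else cbind(Bmat, C)
  if (qr(X)$rank < ncol(X))
    stop("covariate design is collinear with the site indicators")
  Bhat <- solve(crossprod(X), crossprod(X, Y))
  idx_site <- seq_len(ncol(Bmat))
  gamma_reg <- Bhat[idx_site, , drop = FALSE]
  beta <- if (is.null(C)) NULL else Bhat[-idx_site, , drop = FALSE]
  alpha <- colSums(gamma_reg * (n_i / n))
  fitted_full <- X %*% Bhat
  sigma2 <- colMeans((Y - fitted_full)^2)   # pooled, /n so that single-site
  sigma <- sqrt(sigma2)                     # delta_hat is exactly 1
  stand_mean <- matrix(alpha, n, length(regions), byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% beta
  Z <- (Y - stand_mean) / matrix(sigma, n, length(regions), byrow = TRUE)

  I <- length(sites)
  V <- length(regions)
  gamma_hat <- matrix(NA_real_, I, V, dimnames = list(sites, regions))
  delta2_hat <- gamma_hat
  for (i in seq_len(I)) {
    rows <- which(site == sites[i])
    gamma_hat[i, ] <- colMeans(Z[rows, , drop = FALSE])
    delta2_hat[i, ] <- colMeans(sweep(Z[rows, , drop = FALSE], 2,
                                      gamma_hat[i, ])^2)
  }

  priors <- NULL
  if (eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    priors <- vector("list", I)
    names(priors) <- sites
    for (i in seq_len(I)) {
      g <- gamma_hat[i, ]
      d2 <- delta2_hat[i, ]
      gbar <- mean(g)
      tau2 <- stats::var(g)
      if (!is.finite(tau2)) tau2 <- 0
      m <- mean(d2)
      s2 <- stats::var(d2)
      degenerate <- !is.finite(s2) || s2 < 1e-12
      lambda <- if (degenerate) NA_real_ else (2 * s2 + m^2) / s2
      theta <- if (degenerate) NA_real_ else (m * s2 + m^3) / s2
      priors[[i]] <- list(gamma_bar = gbar, tau2 = tau2,
                          lambda = lambda, theta = theta)
      g_new <- g
      d2_new <- d2
      for (it in seq_len(max_iter)) {
        g_old <- g_new
        d2_old <- d2_new
        g_new <- (n_i[i] * tau2 * g + d2_new * gbar) /
          (n_i[i] * tau2 + d2_new)
        if (!degenerate) {
          ssq <- n_i[i] * d2 + n_i[i] * (g - g_new)^2
          d2_new <- (theta + 0.5 * ssq) / (n_i[i] / 2 + lambda - 1)
        }
        if (max(abs(g_new - g_old), abs(d2_new - d2_old)) < tol) break
      }
      gamma_star[i, ] <- g_new
      delta2_star[i, ] <- d2_new
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }
  structure(list(regions = regions, sites = sites, n_site = n_i,
                 design = design, eb = eb,
                 alpha = alpha, beta = beta, sigma = sigma,
                 gamma_hat = gamma_hat, delta_hat = sqrt(delta2_hat),
                 gamma_star = gamma_star, delta_star = sqrt(delta2_star),
                 priors = priors),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("<combat_model> ", length(x$sites), " site(s), ", length(x$regions),
      " regions, EB = ", x$eb, "\n", sep = "")
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Standardizes each region with the stored pooled parameters, removes the
#' (posterior) site location and scale, and restores the covariate
#' structure: y* = sigma * (z - gamma*) / delta* + alpha + X beta. Row count
#' and covariate columns are never altered.
#'
#' @param model A `combat_model`.
#' @param table A `cohort_table` whose `site_id`s are all known to the model.
#' @return The harmonized `cohort_table`.
#' @export
apply_combat <- function(model, table) {
  unknown <- setdiff(unique(table$site_id), model$sites)
  if (length(unknown))
    stop("site(s) not seen at fit time: ", paste(unknown, collapse = ", "))
  regions <- model$regions
  Y <- as.matrix(table[, regions, drop = FALSE])
  n <- nrow(Y)
  C <- .combat_covariates(model$design, table)
  stand_mean <- matrix(model$alpha, n, length(regions), byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% model$beta
  sig <- matrix(model$sigma, n, length(regions), byrow = TRUE)
  Z <- (Y - stand_mean) / sig
  i <- match(table$site_id, model$sites)
  Zadj <- (Z - model$gamma_star[i, , drop = FALSE]) /
    model$delta_star[i, , drop = FALSE]
  out <- table
  out[, regions] <- Zadj * sig + stand_mean
  out
}
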