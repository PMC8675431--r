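# LMS (Box-Cox Cole-Green) normative centile estimation.
#
# Three smooth age curves - Box-Cox power L(t), median M(t), coefficient of
# variation S(t) - are estimated by penalized maximum likelihood with cubic
# P-splines (20 interior knots, second-order difference penalty), the
# penalty of each curve tuned to a target effective df. Backfitting uses
# Fisher scoring with the BCCG expected information for M and S; the L
# curve defaults to a constant solved by direct profile optimization.

.pspline_knots <- function(lo, hi, n_knots = 20, degree = 3) {
  inner <- seq(lo, hi, length.out = n_knots + 2)
  step <- inner[2] - inner[1]
  c(lo - step * (degree:1), inner, hi + step * (1:degree))
}

.pspline_basis <- function(x, knots, degree = 3) {
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
}

.diff_penalty <- function(K, order = 2) {
  D <- diff(diag(K), differences = order)
  crossprod(D)
}

# penalized weighted least squares with the penalty tuned to a target edf
.pwls <- function(B, w, z, P, target_edf) {
  A <- crossprod(B, B * w)
  ridge <- 1e-10 * mean(diag(A))
  diag(A) <- diag(A) + ridge
  Bwz <- crossprod(B, w * z)
  K <- ncol(B)
  if (target_edf >= K - 1e-8) {
    beta <- solve(A, Bwz)
    return(list(beta = beta, edf = K, lambda = 0))
  }
  R <- chol(A)
  S <- forwardsolve(t(R), t(forwardsolve(t(R), P)))
  ev <- pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
  edf_of <- function(loglam) sum(1 / (1 + exp(loglam) * ev))
  null_dim <- sum(ev < 1e-12)
  if (target_edf <= null_dim + 1e-8) {
    loglam <- 30
  } else {
    loglam <- stats::uniroot(function(l) edf_of(l) - target_edf,
                             lower = -25, upper = 30, tol = 1e-8)$root
  }
  lam <- exp(loglam)
  beta <- solve(A + lam * P, Bwz)
  list(beta = beta, edf = edf_of(loglam), lambda = lam)
}

# BCCG transforms and log-likelihood -------------------------------------

.bccg_z <- function(y, mu, sigma, lambda) {
  n <- max(length(y), length(mu), length(sigma), length(lambda))
  r <- rep_len(y, n) / rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  lambda <- rep_len(lambda, n)
  z <- numeric(n)
  nz <- abs(lambda) > 1e-7
  z[nz] <- (r[nz]^lambda[nz] - 1) / (lambda[nz] * sigma[nz])
  z[!nz] <- log(r[!nz]) / sigma[!nz]
  z
}

.bccg_loglik <- function(y, mu, sigma, lambda) {
  z <- .bccg_z(y, mu, sigma, lambda)
  sum((lambda - 1) * log(y) - lambda * log(mu) - log(sigma) -
        0.5 * log(2 * pi) - z^2 / 2)
}

.bccg_loglik_i <- function(y, mu, sigma, lambda) {
  z <- .bccg_z(y, mu, sigma, lambda)
  (lambda - 1) * log(y) - lambda * log(mu) - log(sigma) -
    0.5 * log(2 * pi) - z^2 / 2
}

#' Control parameters for the LMS fitter
#'
#' @param max_iter Maximum backfitting iterations, default 200.
#' @param tol_ll Absolute log-likelihood convergence tolerance; default
#'   `1e-3 + 1e-6 * n` scales mildly with sample size.
#' @param sigma_bounds Admissible range of the fitted coefficient of
#'   variation.
#' @param lambda_bounds Admissible range of the Box-Cox power.
#' @return List of control values.
#' @export
lms_control <- function(max_iter = 200, tol_ll = NULL,
                        sigma_bounds = c(1e-4, 2),
                        lambda_bounds = c(-4, 4)) {
  list(max_iter = max_iter, tol_ll = tol_ll,
       sigma_bounds = sigma_bounds, lambda_bounds = lambda_bounds)
}

.lms_fit_fixed <- function(ages, y, df_l, df_m, df_s, knots, degree,
                           control) {
  B <- .pspline_basis(ages, knots, degree)
  K <- ncol(B)
  P <- .diff_penalty(K)
  n <- length(y)
  tol <- if (is.null(control$tol_ll)) 1e-3 + 1e-6 * n else control$tol_ll
  sb <- control$sigma_bounds
  lb <- control$lambda_bounds

  # initialization: median curve from a penalized fit of log y, constant S
  fm <- .pwls(B, rep(1, n), log(y), P, df_m)
  cm <- fm$beta
  mu <- exp(drop(B %*% cm))
  s0 <- min(max(stats::sd(y / mu - 1), sb[1] * 2), 0.9)
  fs <- .pwls(B, rep(1, n), rep(log(s0), n), P, df_s)
  cs <- fs$beta
  lambda_scalar <- 1
  cl <- NULL
  if (df_l > 1) {
    fl <- .pwls(B, rep(1, n), rep(1, n), P, df_l)
    cl <- fl$beta
  }
  edf <- c(lambda = df_l, mu = fm$edf, sigma = fs$edf)

  lam_vec <- function() {
    if (df_l > 1) pmin(pmax(drop(B %*% cl), lb[1]), lb[2])
    else rep(lambda_scalar, n)
  }
  sig_vec <- function() pmin(pmax(exp(drop(B %*% cs)), sb[1]), sb[2])

  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    # M update (log link): score z/sigma + l(z^2-1), expected info
    # (1 + 2 l^2 sigma^2)/sigma^2
    l <- lam_vec(); sig <- sig_vec(); mu <- exp(drop(B %*% cm))
    z <- .bccg_z(y, mu, sig, l)
    score <- z / sig + l * (z^2 - 1)
    w <- (1 + 2 * l^2 * sig^2) / sig^2
    fm <- .pwls(B, w, drop(B %*% cm) + score / w, P, df_m)
    cm <- fm$beta

    # S update (log link): score z^2 - 1, expected info 2
    mu <- exp(drop(B %*% cm)); sig <- sig_vec()
    z <- .bccg_z(y, mu, sig, l)
    score <- z^2 - 1
    fs <- .pwls(B, rep(2, n), drop(B %*% cs) + score / 2, P, df_s)
    cs <- fs$beta

    # L update: profile optimization (constant) or scoring with the
    # Cole-Green expected information 7 sigma^2 / 4
    sig <- sig_vec()
    if (df_l == 1) {
      opt <- stats::optimize(function(lm)
        .bccg_loglik(y, mu, sig, lm), interval = lb, maximum = TRUE,
        tol = 1e-6)
      lambda_scalar <- opt$maximum
      edf["lambda"] <- 1
    } else {
      l <- lam_vec()
      h <- 1e-4
      score <- (.bccg_loglik_i(y, mu, sig, l + h) -
                  .bccg_loglik_i(y, mu, sig, l - h)) / (2 * h)
      w <- 7 * sig^2 / 4 + 1e-8
      fl <- .pwls(B, w, drop(B %*% cl) + score / w, P, df_l)
      cl <- fl$beta
      edf["lambda"] <- fl$edf
    }
    edf["mu"] <- fm$edf
    edf["sigma"] <- fs$edf

    l <- lam_vec(); sig <- sig_vec(); mu <- exp(drop(B %*% cm))
    ll <- .bccg_loglik(y, mu, sig, l)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    stop("LMS fit did not converge in ", control$max_iter,
         " iterations (last |delta loglik| = ",
         signif(abs(ll - ll_old), 3), ", n = ", n, ", df = (",
         df_l, ", ", df_m, ", ", df_s, "))")
  list(cl = cl, lambda_scalar = lambda_scalar, cm = cm, cs = cs,
       loglik = ll, edf = edf, iterations = iter, df = c(df_l, df_m, df_s))
}

#' Fit an LMS (Box-Cox Cole-Green) centile model
#'
#' Estimates smooth lambda(t), mu(t), sigma(t) curves for a positive
#' response against age by penalized BCCG maximum likelihood. With
#' `edf = "auto"`, effective degrees of freedom are chosen by a coordinate
#' grid search (mu and sigma over 2..8, lambda over 1..3) minimizing
#' GAIC = -2 loglik + k * total edf.
#'
#' @param ages Ages in years.
#' @param values Positive response values (mm), same length; n >= 50.
#' @param edf Named numeric vector `c(lambda=, mu=, sigma=)` of target
#'   effective df, or `"auto"`.
#' @param gaic_k GAIC penalty per effective df, default 2 (AIC).
#' @param n_knots Interior P-spline knots, default 20.
#' @param control A [lms_control()] list.
#' @return Object of class `lms_model`.
#' @export
fit_lms <- function(ages, values, edf = c(lambda = 1, mu = 4, sigma = 2),
                    gaic_k = 2, n_knots = 20, control = lms_control()) {
  if (length(ages) != length(values)) stop("ages/values length mismatch")
  if (length(values) < 50) stop("need at least 50 observations")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  if (any(!is.finite(ages))) stop("ages must be finite")
  support <- range(ages)
  degree <- 3
  knots <- .pspline_knots(support[1], support[2], n_knots, degree)

  make_model <- function(fit) {
    total_edf <- sum(fit$edf)
    structure(list(knots = knots, degree = degree, support = support,
                   cl = fit$cl, lambda_scalar = fit$lambda_scalar,
                   cm = fit$cm, cs = fit$cs,
                   df_target = c(lambda = fit$df[1], mu = fit$df[2],
                                 sigma = fit$df[3]),
                   edf = fit$edf, total_edf = total_edf,
                   loglik = fit$loglik, gaic_k = gaic_k,
                   gaic = -2 * fit$loglik + gaic_k * total_edf,
                   iterations = fit$iterations, n = length(values),
                   control = control),
              class = "lms_model")
  }
  if (identical(edf, "auto")) {
    fit1 <- function(dl, dm, ds) {
      tryCatch(.lms_fit_fixed(ages, values, dl, dm, ds, knots, degree,
                              control),
               error = function(e) NULL)
    }
    gaic_of <- function(f) if (is.null(f)) Inf
                           else -2 * f$loglik + gaic_k * sum(f$edf)
    dl <- 1; ds <- 2
    fits_m <- lapply(2:8, function(dm) fit1(dl, dm, ds))
    dm <- (2:8)[which.min(vapply(fits_m, gaic_of, numeric(1)))]
    fits_s <- lapply(2:8, function(ds2) fit1(dl, dm, ds2))
    ds <- (2:8)[which.min(vapply(fits_s, gaic_of, numeric(1)))]
    fits_l <- lapply(1:3, function(dl2) fit1(dl2, dm, ds))
    dl <- (1:3)[which.min(vapply(fits_l, gaic_of, numeric(1)))]
    best <- fit1(dl, dm, ds)
    if (is.null(best)) stop("GAIC search found no estimable configuration")
    mod <- make_model(best)
    mod$gaic_search <- c(lambda = dl, mu = dm, sigma = ds)
    mod
  } else {
    stopifnot(is.numeric(edf), length(edf) == 3)
    if (is.null(names(edf))) names(edf) <- c("lambda", "mu", "sigma")
    make_model(.lms_fit_fixed(ages, values, edf[["lambda"]], edf[["mu"]],
                              edf[["sigma"]], knots, degree, control))
  }
}

#' @export
print.lms_model <- function(x, ...) {
  cat("<lms_model> n = ", x$n, ", edf = (",
      paste(round(x$edf, 2), collapse = ", "),
      "), loglik = ", round(x$loglik, 2),
      ", GAIC(", x$gaic_k, ") = ", round(x$gaic, 2), "\n", sep = "")
  invisible(x)
}

#' Evaluate the L, M, S curves of a fitted model
#'
#' Out-of-support ages are refused rather than extrapolated.
#'
#' @param model An `lms_model`.
#' @param ages Ages within the fitting support.
#' @return Data frame with columns `age`, `lambda`, `mu`, `sigma`.
#' @export
predict_lms <- function(model, ages) {
  eps <- 1e-9
  if (any(ages < model$support[1] - eps | ages > model$support[2] + eps))
    stop("age(s) outside the fitted support [",
         round(model$support[1], 2), ", ", round(model$support[2], 2), "]")
  ages <- pmin(pmax(ages, model$support[1]), model$support[2])
  B <- .pspline_basis(ages, model$knots, model$degree)
  ctl <- model$control
  lambda <- if (!is.null(model$cl))
    pmin(pmax(drop(B %*% model$cl), ctl$lambda_bounds[1]),
         ctl$lambda_bounds[2])
  else rep(model$lambda_scalar, length(ages))
  sigma <- pmin(pmax(exp(drop(B %*% model$cs)), ctl$sigma_bounds[1]),
                ctl$sigma_bounds[2])
  data.frame(age = ages, lambda = lambda,
             mu = exp(drop(B %*% model$cm)), sigma = sigma)
}

#' Centile curve of a fitted LMS model
#'
#' C_alpha(t) = M(t) (1 + L(t) S(t) z_alpha)^(1/L(t)) for L != 0 and
#' M(t) exp(S(t) z_alpha) for L = 0, with z_alpha the standard-normal
#' quantile of `alpha` percent.
#'
#' @param model An `lms_model`.
#' @param alpha Centile in percent, in (0, 100).
#' @param ages Evaluation ages (default 200 points across the support).
#' @return Numeric vector of centile values (mm).
#' @export
centile_curve <- function(model, alpha, ages = NULL) {
  if (alpha <= 0 || alpha >= 100) stop("alpha must be in (0, 100) percent")
  if (is.null(ages))
    ages <- seq(model$support[1], model$support[2], length.out = 200)
  p <- predict_lms(model, ages)
  z <- stats::qnorm(alpha / 100)
  arg <- 1 + p$lambda * p$sigma * z
  nz <- abs(p$lambda) > 1e-7
  if (any(arg[nz] <= 0))
    stop("centile undefined (non-positive power argument) at age(s) ",
         paste(round(ages[nz & arg <= 0], 1), collapse = ", "))
  out <- numeric(length(ages))
  out[nz] <- p$mu[nz] * arg[nz]^(1 / p$lambda[nz])
  out[!nz] <- p$mu[!nz] * exp(p$sigma[!nz] * z)
  out
}

#' z-score of an observation under a fitted LMS model
#'
#' Inverse of the centile transform; round-trips with [centile_curve()].
#'
#' @param model An `lms_model`.
#' @param age Age(s) within support.
#' @param y Positive observed value(s) (mm).
#' @return z-score(s).
#' @export
z_score <- function(model, age, y) {
  if (any(y <= 0)) stop("y must be positive")
  p <- predict_lms(model, age)
  .bccg_z(y, p$mu, p$sigma, p$lambda)
}

#' Normative centile tables by region and sex
#'
#' Fits one LMS model per region and sex stratum and evaluates the 13
#' standard centiles on an age grid (restricted to each stratum's observed
#' age range; no extrapolation). Strata with fewer than `min_n` subjects are
#' skipped with a warning. Monotonicity of the centile columns is asserted
#' at every grid age.
#'
#' @param table A `cohort_table`.
#' @param regions Region columns (default all).
#' @param grid Age grid, default 3 to 90 by 0.5 years.
#' @param centiles Centile levels in percent.
#' @param edf Target effective df passed to [fit_lms()], or `"auto"`.
#' @param gaic_k GAIC penalty, default 2.
#' @param min_n Minimum stratum size, default 50.
#' @return Data frame: `region`, `hemisphere`, `sex`, `age`, then one
#'   column per centile (`c0.4` ... `c99.6`), plus an attribute `models`.
#' @export
build_centile_tables <- function(table, regions = NULL,
                                 grid = seq(3, 90, by = 0.5),
                                 centiles = c(0.4, 1, 2.5, 5, 10, 25, 50,
                                              75, 90, 95, 97.5, 99, 99.6),
                                 edf = c(lambda = 1, mu = 4, sigma = 2),
                                 gaic_k = 2, min_n = 50) {
  if (is.null(regions)) regions <- cohort_regions(table)
  registry <- attr(table, "registry")
  out <- list()
  models <- list()
  for (rg in regions) {
    hemi <- if (!is.null(registry)) registry$hemisphere[
      match(rg, registry$label)] else NA_character_
    for (sx in c("male", "female")) {
      sel <- table$sex == sx
      if (sum(sel) < min_n) {
        warning("stratum ", rg, "/", sx, " has n = ", sum(sel),
                " < ", min_n, "; skipped")
        next
      }
      ages <- table$age[sel]
      mod <- fit_lms(ages, table[[rg]][sel], edf = edf, gaic_k = gaic_k)
      g <- grid[grid >= min(ages) & grid <= max(ages)]
      cv <- vapply(centiles, function(a) centile_curve(mod, a, g),
                   numeric(length(g)))
      if (any(apply(cv, 1, function(r) any(diff(r) <= 0))))
        stop("centile columns are not strictly increasing for ", rg,
             "/", sx)
      colnames(cv) <- paste0("c", centiles)
      out[[paste(rg, sx)]] <- cbind(
        data.frame(region = rg, hemisphere = hemi, sex = sx, age = g,
                   stringsAsFactors = FALSE),
        as.data.frame(cv))
      models[[paste(rg, sx)]] <- mod
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "models") <- models
  res
}
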