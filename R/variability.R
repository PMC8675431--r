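# Interindividual variability: residual dispersion by age group with
# one-way ANOVA on log squared residuals, bias-corrected lnSD effects, and
# DerSimonian-Laird random-effects pooling across sites.

#' Residual dispersion differences across age groups
#'
#' Converts each residual of the selected FP model into a per-subject
#' dispersion score ln(e^2 + eps) - the log transform counteracting the
#' right skew of squared residuals - and tests for age-group differences
#' with a one-way ANOVA on these scores. Per-group mean squared residuals
#' (sum e^2 / n_t) are reported untransformed alongside.
#'
#' @param residuals Numeric residual vector.
#' @param groups Group labels (factor or character), one per residual.
#' @param eps Stabilizing constant inside the log, default 1e-12.
#' @param threshold Bonferroni threshold for the significance flag,
#'   default 0.0007 (68 regions x 3 age groups).
#' @return List with the per-group summary table, `F`, `p`, `significant`.
#' @export
residual_dispersion <- function(residuals, groups, eps = 1e-12,
                                threshold = 0.0007) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  n_t <- table(droplevels(groups))
  if (any(n_t < 2)) stop("every group needs at least 2 residuals")
  score <- log(residuals^2 + eps)
  fit <- stats::lm(score ~ groups)
  av <- stats::anova(fit)
  per_group <- data.frame(
    group = names(n_t), n = as.integer(n_t),
    mean_sq_residual = as.numeric(tapply(residuals^2, droplevels(groups),
                                         mean)),
    mean_log_score = as.numeric(tapply(score, droplevels(groups), mean)),
    stringsAsFactors = FALSE)
  f <- av$`F value`[1]
  p <- av$`Pr(>F)`[1]
  list(per_group = per_group, F = f, df1 = av$Df[1], df2 = av$Df[2],
       p = p, significant = p < threshold, threshold = threshold)
}

#' Bias-corrected log-SD effect size
#'
#' effect = ln(sd) + 1/(2(n-1)), sampling variance 1/(2(n-1)): the standard
#' meta-analytic effect for a sample standard deviation.
#'
#' @param sd Sample standard deviation (> 0), in mm.
#' @param n Sample size (>= 2).
#' @return List with `effect` and `variance`.
#' @examples
#' lnsd_effect(1, 11)  # effect 0.05, variance 0.05
#' @export
lnsd_effect <- function(sd, n) {
  if (any(n < 2)) stop("n must be at least 2")
  if (any(sd <= 0)) stop("sd must be positive")
  list(effect = log(sd) + 1 / (2 * (n - 1)),
       variance = 1 / (2 * (n - 1)))
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' tau^2 = max(0, (Q - (k-1)) / c) with c = sum(w) - sum(w^2)/sum(w) on
#' fixed-effect weights w = 1/v; pooled effect is the inverse-variance mean
#' with weights 1/(v + tau^2) and a 95% normal confidence interval.
#'
#' @param effects Per-study effects (e.g. bias-corrected lnSD).
#' @param variances Per-study sampling variances (> 0).
#' @return List with `estimate`, `ci` (length 2), `tau2`, `se`, `k`, and
#'   `pooled_sd = exp(estimate)` for lnSD effects.
#' @export
meta_pool <- function(effects, variances) {
  if (length(effects) != length(variances))
    stop("effects and variances must have equal length")
  if (!length(effects)) stop("need at least 1 study")
  if (any(variances <= 0)) stop("variances must be positive")
  w <- 1 / variances
  k <- length(effects)
  if (k == 1) {
    tau2 <- 0
  } else {
    mu_fe <- sum(w * effects) / sum(w)
    Q <- sum(w * (effects - mu_fe)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / cc)
  }
  w_re <- 1 / (variances + tau2)
  est <- sum(w_re * effects) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  list(estimate = est, se = se,
       ci = c(est - 1.96 * se, est + 1.96 * se),
       tau2 = tau2, k = k, pooled_sd = exp(est))
}

#' Meta-analysis of per-site SDs for one region
#'
#' Within each age group, computes the per-site SD of a regional thickness,
#' converts it to the bias-corrected lnSD effect and pools across sites with
#' [meta_pool()]. `exp(pooled lnSD)` is the headline pooled SD in mm.
#'
#' @param table A `cohort_table`.
#' @param region Region column name.
#' @param groups An [age_group_def()].
#' @param min_n Minimum per-site cell size, default 5.
#' @return Data frame, one row per age group, with pooled SD, CI and tau2.
#' @export
site_sd_meta <- function(table, region, groups = age_group_def(),
                         min_n = 5) {
  grp <- assign_age_group(table$age, groups)
  out <- lapply(levels(grp), function(g) {
    sel <- grp == g
    sds <- tapply(table[[region]][sel], table$site_id[sel], stats::sd)
    ns <- tapply(table[[region]][sel], table$site_id[sel], length)
    keep <- !is.na(sds) & ns >= min_n & sds > 0
    if (!any(keep)) return(NULL)
    ef <- lnsd_effect(as.numeric(sds[keep]), as.numeric(ns[keep]))
    mp <- meta_pool(ef$effect, ef$variance)
    data.frame(region = region, group = g, k_sites = mp$k,
               pooled_lnsd = mp$estimate, tau2 = mp$tau2,
               pooled_sd = mp$pooled_sd,
               sd_ci_low = exp(mp$ci[1]), sd_ci_high = exp(mp$ci[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Association between regional variability and surface area
#'
#' Spearman rank correlation between per-region pooled SDs and mean surface
#' areas, probing whether dispersion is larger in smaller (harder to
#' measure) regions. Degenerate constant input yields rho = 0 with a
#' warning.
#'
#' @param pooled_sd Per-region pooled SD (mm).
#' @param mean_area Per-region mean surface area (mm^2), same length.
#' @return List with `rho` and `p`.
#' @export
sd_vs_area <- function(pooled_sd, mean_area) {
  if (length(pooled_sd) != length(mean_area))
    stop("pooled_sd and mean_area must have equal length")
  if (stats::sd(pooled_sd) == 0 || stats::sd(mean_area) == 0) {
    warning("constant input; rank correlation undefined, reporting rho = 0")
    return(list(rho = 0, p = 1))
  }
  ct <- suppressWarnings(
    stats::cor.test(pooled_sd, mean_area, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
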