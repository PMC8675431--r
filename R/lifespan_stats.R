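# Age-group Pearson correlations between age and regional thickness, and
# male/female comparison of correlations via the independent-groups Fisher
# z test (the applicable comparison family for disjoint sex samples).

#' Age-thickness correlations by age group and sex stratum
#'
#' Pearson correlation between age and each regional thickness within each
#' lifespan age group, for all subjects and separately per sex. Cells with
#' fewer than `min_n` subjects are omitted with a warning.
#'
#' @param table A `cohort_table`.
#' @param groups An [age_group_def()].
#' @param regions Region columns (default all).
#' @param min_n Minimum cell size, default 4.
#' @return Data frame with columns `region`, `group`, `stratum`, `r`, `n`.
#' @export
agegroup_correlations <- function(table, groups = age_group_def(),
                                  regions = NULL, min_n = 4) {
  if (is.null(regions)) regions <- cohort_regions(table)
  grp <- assign_age_group(table$age, groups)
  strata <- list(all = rep(TRUE, nrow(table)),
                 male = table$sex == "male",
                 female = table$sex == "female")
  rows <- list()
  skipped <- 0L
  for (g in levels(grp)) {
    for (s in names(strata)) {
      sel <- grp == g & strata[[s]]
      n <- sum(sel)
      if (n < min_n) { skipped <- skipped + length(regions); next }
      age <- table$age[sel]
      for (rg in regions) {
        rows[[length(rows) + 1L]] <-
          data.frame(region = rg, group = g, stratum = s,
                     r = stats::cor(age, table[[rg]][sel]), n = n,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0)
    warning(skipped, " region x group x stratum cell(s) omitted (n < ",
            min_n, ")")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two independent Pearson correlations (Fisher z)
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), with a two-sided
#' normal p-value; the comparison used to contrast male and female
#' age-thickness correlations.
#'
#' @param r1,r2 Correlations in (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` and `p`.
#' @examples
#' compare_correlations(0.5, 103, 0.3, 103)
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both samples need n > 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Male-female comparison of age-thickness correlations
#'
#' Runs [compare_correlations()] for every region x age-group cell with
#' adequate male and female samples. Significance is flagged at the supplied
#' regional threshold (the printed thresholds are configurable constants,
#' default 0.0007 as used for the early-life comparisons).
#'
#' @param table A `cohort_table`.
#' @param groups An [age_group_def()].
#' @param regions Region columns (default all).
#' @param threshold Two-sided p-value threshold for the `significant` flag.
#' @param min_n Minimum per-sex cell size, default 4.
#' @return Data frame with r/n per sex, `z`, `p` and `significant`.
#' @export
sex_correlation_comparison <- function(table, groups = age_group_def(),
                                       regions = NULL, threshold = 0.0007,
                                       min_n = 4) {
  cors <- agegroup_correlations(table, groups, regions, min_n = min_n)
  m <- cors[cors$stratum == "male", ]
  f <- cors[cors$stratum == "female", ]
  key <- function(d) paste(d$region, d$group)
  common <- intersect(key(m), key(f))
  m <- m[match(common, key(m)), ]
  f <- f[match(common, key(f)), ]
  zp <- mapply(function(r1, n1, r2, n2) {
    ct <- compare_correlations(r1, n1, r2, n2)
    c(ct$z, ct$p)
  }, m$r, m$n, f$r, f$n)
  out <- data.frame(region = m$region, group = m$group,
                    r_male = m$r, n_male = m$n,
                    r_female = f$r, n_female = f$n,
                    z = zp[1, ], p = zp[2, ],
                    significant = zp[2, ] < threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
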