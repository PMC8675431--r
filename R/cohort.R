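#' Age-group definition for lifespan analyses
#'
#' Early, middle and late life age groups. The printed group labels are the
#' integer years 3-29, 30-59 and 60-90; real-valued ages are assigned by the
#' half-open intervals [3,30), [30,60), [60,90] so that every age in [3,90]
#' belongs to exactly one group and the group a given integer year maps to
#' matches the printed labels.
#'
#' @param breaks Numeric vector of interior boundaries (default `c(30, 60)`).
#' @param bounds Overall closed age support (default `c(3, 90)`).
#' @param labels Group labels, one more than `length(breaks)`.
#' @return An object of class `age_group_def`.
#' @export
age_group_def <- function(breaks = c(30, 60), bounds = c(3, 90),
                          labels = c("early", "middle", "late")) {
  stopifnot(length(labels) == length(breaks) + 1L,
            all(diff(c(bounds[1], breaks, bounds[2])) > 0))
  out <- list(breaks = breaks, bounds = bounds, labels = labels)
  class(out) <- "age_group_def"
  out
}

#' @export
print.age_group_def <- function(x, ...) {
  edges <- c(x$bounds[1], x$breaks, x$bounds[2])
  cat("<age_group_def>\n")
  for (i in seq_along(x$labels))
    cat("  ", x$labels[i], ": [", edges[i], ", ", edges[i + 1],
        if (i < length(x$labels)) ")" else "]", "\n", sep = "")
  invisible(x)
}

#' Assign ages to lifespan age groups
#'
#' @param age Numeric vector of ages in years.
#' @param def An [age_group_def()].
#' @return Factor of group labels, one per age.
#' @examples
#' assign_age_group(c(29, 30, 90))
#' @export
assign_age_group <- function(age, def = age_group_def()) {
  if (any(!is.finite(age)) || any(age < def$bounds[1] | age > def$bounds[2]))
    stop("ages must lie within [", def$bounds[1], ", ", def$bounds[2], "]")
  edges <- c(def$bounds[1], def$breaks, def$bounds[2])
  idx <- findInterval(age, edges, rightmost.closed = TRUE)
  factor(def$labels[idx], levels = def$labels)
}

#' Median-absolute-deviation outlier flags
#'
#' Flags values lying more than `k` raw median absolute deviations from the
#' median, the quality-control rule applied per site and region before
#' pooling multi-site thickness tables. When the MAD is zero (at least half
#' the values identical) any value different from the median is flagged, so
#' the rule degrades gracefully instead of dividing by zero.
#'
#' @param values Numeric vector (>= 3 finite values required).
#' @param k MAD multiplier, default 5.
#' @return Logical vector, `TRUE` for flagged values (`NA` in, `NA` out).
#' @examples
#' flag_outliers_mad(c(1:9, 1000))
#' @export
flag_outliers_mad <- function(values, k = 5) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("need at least 3 finite values to flag outliers")
  med <- stats::median(values[ok])
  dev <- abs(values - med)
  mad <- stats::median(dev[ok])  # raw MAD, no consistency constant
  flag <- if (mad > 0) dev > k * mad else dev > 0
  flag[!ok & !is.na(values)] <- TRUE   # infinities are always outliers
  flag
}

.required_cols <- c("subject_id", "site_id", "sex", "age")

.parse_sex <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("f", "female")] <- "female"
  out[s %in% c("m", "male")] <- "male"
  out
}

#' Construct a validated cohort table
#'
#' Validates an in-memory data frame as a subject-level cohort table: one row
#' per subject with `subject_id`, `site_id`, `sex` (`male`/`female`, or coded
#' `M`/`F`), `age` in years, and one thickness column per registry region
#' (optionally matching surface-area columns). Rows failing any invariant
#' (unparseable sex, age outside bounds, any missing required value,
#' duplicated subject id) are dropped and counted; analyses use complete
#' cases only.
#'
#' @param df A data frame.
#' @param registry A [region_registry()] naming the 68 thickness columns.
#' @param age_bounds Closed admissible age range, default `c(3, 90)`.
#' @param area_registry Optional registry of surface-area columns; kept if
#'   present in `df`.
#' @return A `cohort_table` (data frame) with attributes `regions`,
#'   `area_regions` and `exclusions` (named counts of dropped rows).
#' @export
as_cohort_table <- function(df, registry = region_registry(),
                            age_bounds = c(3, 90),
                            area_registry = region_registry("surfavg")) {
  missing_cols <- setdiff(c(.required_cols, registry$label), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  area_cols <- intersect(area_registry$label, names(df))
  keep_cols <- c(.required_cols, registry$label, area_cols)
  df <- df[, keep_cols, drop = FALSE]

  excl <- c(bad_sex = 0L, bad_age = 0L, incomplete = 0L, duplicate_id = 0L)
  df$sex <- .parse_sex(df$sex)
  bad_sex <- is.na(df$sex)
  df$age <- suppressWarnings(as.numeric(df$age))
  bad_age <- !is.finite(df$age) | df$age < age_bounds[1] | df$age > age_bounds[2]
  for (cl in c(registry$label, area_cols))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  vals <- as.matrix(df[, registry$label, drop = FALSE])
  incomplete <- !stats::complete.cases(df[, c(.required_cols, registry$label)]) |
    rowSums(!is.finite(vals) | vals <= 0) > 0
  excl["bad_sex"] <- sum(bad_sex)
  excl["bad_age"] <- sum(bad_age & !bad_sex)
  excl["incomplete"] <- sum(incomplete & !bad_sex & !bad_age)
  drop <- bad_sex | bad_age | incomplete
  df <- df[!drop, , drop = FALSE]
  dup <- duplicated(df$subject_id)
  excl["duplicate_id"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (sum(excl) > 0)
    message("as_cohort_table: excluded ", sum(excl), " row(s) [",
            paste(names(excl), excl, sep = "=", collapse = ", "), "]")
  df$subject_id <- as.character(df$subject_id)
  df$site_id <- as.character(df$site_id)
  rownames(df) <- NULL
  structure(df,
            regions = registry$label,
            registry = registry,
            area_regions = area_cols,
            age_bounds = age_bounds,
            exclusions = excl,
            class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from delimited text
#'
#' Reads a UTF-8 delimiter-separated subject-level table and validates it via
#' [as_cohort_table()]. A missing required column is a hard error naming the
#' column; rows with unparseable or out-of-bounds values are excluded with a
#' logged count.
#'
#' @param path Path to a CSV (or other delimited) file with a header.
#' @param registry A [region_registry()].
#' @param sep Field separator, default `","`.
#' @inheritParams as_cohort_table
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, registry = region_registry(), sep = ",",
                        age_bounds = c(3, 90)) {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  as_cohort_table(df, registry = registry, age_bounds = age_bounds)
}

#' Write a cohort table to CSV
#'
#' @param table A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " subjects, ",
      length(attr(x, "regions")), " regions, ",
      length(unique(x$site_id)), " site(s); ages ",
      round(min(x$age), 1), "-", round(max(x$age), 1), ", ",
      round(100 * mean(x$sex == "female")), "% female\n", sep = "")
  invisible(x)
}

#' Thickness columns of a cohort table
#' @param table A `cohort_table`.
#' @return Character vector of region column names.
#' @export
cohort_regions <- function(table) attr(table, "regions")

#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  keep <- attributes(x)[c("regions", "registry", "area_regions",
                          "age_bounds", "exclusions")]
  keep <- keep[!is.na(names(keep))]
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c(.required_cols, keep$regions) %in% names(out))) {
    for (nm in names(keep)) attr(out, nm) <- keep[[nm]]
    class(out) <- c("cohort_table", "data.frame")
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"   # no longer a full cohort table
  }
  out
}

#' Quality control a cohort table
#'
#' Applies the per-site, per-region MAD outlier rule: within each site, a
#' subject's regional value beyond `k` MADs of the site median is set missing,
#' after which subjects with any missing region are removed (listwise
#' deletion, matching the complete-data inclusion rule).
#'
#' @param table A `cohort_table`.
#' @param k MAD multiplier, default 5.
#' @param min_site_n Minimum site size for the MAD rule to be defined
#'   (default 8); smaller sites are passed through unflagged, since a
#'   median/MAD over a handful of subjects flags mostly noise.
#' @return A `cohort_table` with attribute `qc` recording counts of flagged
#'   values and dropped subjects.
#' @export
qc_cohort <- function(table, k = 5, min_site_n = 8) {
  regions <- cohort_regions(table)
  vals <- as.matrix(table[, regions, drop = FALSE])
  n_flagged <- 0L
  for (site in unique(table$site_id)) {
    idx <- which(table$site_id == site)
    if (length(idx) < max(3L, min_site_n)) next
    for (j in seq_along(regions)) {
      fl <- flag_outliers_mad(vals[idx, j], k = k)
      if (any(fl)) {
        vals[idx[fl], j] <- NA_real_
        n_flagged <- n_flagged + sum(fl)
      }
    }
  }
  keep <- rowSums(is.na(vals)) == 0L
  out <- table[keep, , drop = FALSE]
  out[, regions] <- vals[keep, , drop = FALSE]
  attr(out, "qc") <- c(values_flagged = n_flagged,
                       subjects_dropped = sum(!keep))
  rownames(out) <- NULL
  out
}

#' Packaged multi-site cohort characteristics
#'
#' Site-level metadata of the 83 pooled lifespan samples (per-site N, sex
#' split, age mean/SD/range) used both for bookkeeping checks and to
#' calibrate the synthetic cohort generator.
#'
#' @return Data frame with one row per site.
#' @export
site_characteristics <- function() {
  path <- system.file("extdata", "enigma_site_table.csv", package = "cortlife")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
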