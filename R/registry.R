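#' Desikan-Killiany regional atlas names
#'
#' The 34 gyral region labels of the Desikan-Killiany cortical parcellation,
#' in FreeSurfer naming. Combined with the two hemispheres they define the
#' 68 regional thickness measures handled by the package.
#'
#' @return Character vector of 34 region names.
#' @export
dk_region_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
}

#' Region registry for cortical thickness columns
#'
#' Builds the ordered registry of the 68 bilateral Desikan-Killiany thickness
#' variables. Column labels follow the common consortium spreadsheet dialect
#' `<hemi>_<region>_thickavg` with hemisphere prefixes `L`/`R`; an alternative
#' mapping can be supplied for other dialects.
#'
#' @param measure Suffix of the measurement columns (default `"thickavg"`;
#'   use `"surfavg"` for surface areas).
#' @param labels Optional custom character vector of 68 column labels (in
#'   left-34, right-34 order) overriding the default dialect.
#' @return An object of class `region_registry`: a data frame with columns
#'   `label`, `hemisphere` (`"left"`/`"right"`) and `region`.
#' @examples
#' reg <- region_registry()
#' nrow(reg)  # 68
#' @export
region_registry <- function(measure = "thickavg", labels = NULL) {
  regions <- dk_region_names()
  hemi <- rep(c("left", "right"), each = length(regions))
  region <- rep(regions, times = 2)
  if (is.null(labels)) {
    prefix <- rep(c("L", "R"), each = length(regions))
    labels <- paste0(prefix, "_", region, "_", measure)
  }
  if (length(labels) != 68L || anyDuplicated(labels) > 0L)
    stop("a region registry requires 68 unique labels")
  out <- data.frame(label = labels, hemisphere = hemi, region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_registry", "data.frame")
  out
}

#' @export
print.region_registry <- function(x, ...) {
  cat("<region_registry> ", nrow(x), " regions (",
      sum(x$hemisphere == "left"), " left / ",
      sum(x$hemisphere == "right"), " right)\n", sep = "")
  invisible(x)
}

#' Hemisphere of a registry label
#'
#' @param label Character vector of registry labels.
#' @param registry A [region_registry()].
#' @return Character vector `"left"`/`"right"`.
#' @export
region_hemisphere <- function(label, registry = region_registry()) {
  idx <- match(label, registry$label)
  if (anyNA(idx)) stop("unknown region label(s): ",
                       paste(label[is.na(idx)], collapse = ", "))
  registry$hemisphere[idx]
}
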