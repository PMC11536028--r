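#' Built-in composite tau-PET region-of-interest definitions
#'
#' Returns the registry of the ten composite regions of interest (ROIs) used
#' throughout the package: the mesial temporal (`Me`), temporoparietal (`Te`),
#' rest-of-neocortex (`R`) and meta temporal (`MetaT`) composites used for tau
#' quantification, plus the six Braak-stage composites (`BraakI`..`BraakVI`)
#' built from the Desikan-Killiany parcellation and used for topographic tau
#' staging.
#'
#' Region names are stored normalized: lower case, spaces replaced by
#' underscores (see [normalize_region()]). The parahippocampal gyrus appears
#' in both the `Me` and `BraakIII` composites under the single canonical name
#' `"parahippocampal"`.
#'
#' @return A named list of composite definitions. Each element is a list with
#'   fields `name`, `regions` (character vector) and `weights` (equal by
#'   default). The registry itself is rebuilt on each call, so callers cannot
#'   corrupt the built-ins.
#' @examples
#' names(composite_definitions())
#' composite_definitions()$Me$regions
#' @export
composite_definitions <- function() {
  defs <- list(
    Me = c("entorhinal", "hippocampus", "parahippocampal", "amygdala"),
    Te = c(
      "inferior_temporal", "fusiform", "supramarginal", "angular",
      "posterior_cingulate", "precuneus", "superior_parietal",
      "inferior_parietal", "lateral_occipital"
    ),
    R = c(
      "dorsolateral_prefrontal", "ventrolateral_prefrontal", "orbitofrontal",
      "gyrus_rectus", "superior_temporal", "anterior_cingulate"
    ),
    MetaT = c(
      "entorhinal", "hippocampus", "parahippocampal", "amygdala",
      "inferior_temporal", "middle_temporal", "fusiform"
    ),
    BraakI = "entorhinal",
    BraakII = "hippocampus",
    BraakIII = c("parahippocampal", "fusiform", "lingual", "amygdala"),
    BraakIV = c(
      "middle_temporal", "thalamus_proper", "caudal_anterior_cingulate",
      "rostral_anterior_cingulate", "posterior_cingulate", "isthmus_cingulate",
      "insula", "inferior_temporal", "temporal_pole"
    ),
    BraakV = c(
      "superior_frontal", "lateral_orbitofrontal", "medial_orbitofrontal",
      "frontal_pole", "caudal_middle_frontal", "rostral_middle_frontal",
      "parsopercularis", "parsorbitalis", "parstriangularis", "caudate",
      "putamen", "lateral_occipital", "supramarginal", "inferior_parietal",
      "superior_parietal", "superior_temporal", "pallidum", "precuneus",
      "bankssts", "accumbens", "transverse_temporal"
    ),
    BraakVI = c("pericalcarine", "postcentral", "cuneus", "precentral",
                "paracentral")
  )
  purrr::imap(defs, function(regions, name) {
    new_composite(name, regions)
  })
}

#' Construct a composite ROI definition
#'
#' @param name Composite name.
#' @param regions Character vector of atlas region names (normalized via
#'   [normalize_region()]); must be non-empty and free of duplicates.
#' @param weights Optional non-negative per-region weights (default equal);
#'   must match `regions` in length and not all be zero.
#' @return A `composite_definition` list with fields `name`, `regions`,
#'   `weights`.
#' @export
new_composite <- function(name, regions, weights = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  regions <- normalize_region(regions)
  if (length(regions) == 0L) {
    stop("composite '", name, "': region list must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(regions)) {
    stop("composite '", name, "': duplicated region names", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1, length(regions))
  }
  if (length(weights) != length(regions)) {
    stop("composite '", name, "': weights must match regions in length",
         call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("composite '", name, "': weights must be non-negative, not all zero",
         call. = FALSE)
  }
  structure(
    list(name = name, regions = regions, weights = as.numeric(weights)),
    class = "composite_definition"
  )
}

#' Normalize atlas region names
#'
#' Lower-cases region names and replaces spaces, hyphens and slashes with
#' underscores, so CSV headers written with different conventions resolve to
#' the same region.
#'
#' @param x Character vector of region names.
#' @return Normalized character vector.
#' @export
normalize_region <- function(x) {
  gsub("[ /\\-]+", "_", tolower(trimws(x)))
}

#' All atlas regions required by the built-in composite registry
#'
#' @return Sorted character vector of unique region names.
#' @export
required_regions <- function() {
  sort(unique(unlist(purrr::map(composite_definitions(), "regions"))))
}

#' Compute a composite SUVR from regional values
#'
#' The composite standardized uptake value ratio (SUVR) is the weighted mean
#' of the listed regional SUVRs; weights are equal unless the definition says
#' otherwise. Whether research composites are volume-weighted is rarely
#' reported, so the unweighted mean is the documented default and custom
#' weights accommodate volume weighting.
#'
#' @param regional_suvr Named numeric vector (or single-row data frame of
#'   `suvr_<region>` columns) of regional SUVRs; names are normalized before
#'   lookup. All values must be positive.
#' @param definition A composite definition from [composite_definitions()] or
#'   [new_composite()].
#' @return The composite SUVR (positive scalar).
#' @examples
#' compose_suvr(c(entorhinal = 1.2, hippocampus = 1.4, parahippocampal = 1.0,
#'                amygdala = 1.0), composite_definitions()$Me)
#' @export
compose_suvr <- function(regional_suvr, definition) {
  vals <- unlist(regional_suvr)
  names(vals) <- normalize_region(sub("^suvr_", "", names(vals)))
  missing <- setdiff(definition$regions, names(vals))
  if (length(missing) > 0L) {
    stop("composite '", definition$name, "': missing region(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- vals[definition$regions]
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("composite '", definition$name, "': SUVR values must be positive ",
         "and finite", call. = FALSE)
  }
  sum(v * definition$weights) / sum(definition$weights)
}

#' Add composite SUVR columns to a cohort table
#'
#' Takes a cohort with one `suvr_<region>` column per atlas region and appends
#' one column per composite ROI (named `Me`, `Te`, `R`, `MetaT`,
#' `BraakI`..`BraakVI` by default). Records missing a required region are
#' rejected.
#'
#' @param cohort A data frame with `suvr_<region>` columns.
#' @param definitions Registry of composites (default the built-ins).
#' @return The cohort tibble with one extra numeric column per composite.
#' @export
add_composites <- function(cohort, definitions = composite_definitions()) {
  cohort <- tibble::as_tibble(cohort)
  suvr_cols <- grep("^suvr_", names(cohort), value = TRUE)
  have <- normalize_region(sub("^suvr_", "", suvr_cols))
  mat <- as.matrix(cohort[suvr_cols])
  colnames(mat) <- have
  if (any(!is.finite(mat)) || any(mat <= 0)) {
    stop("regional SUVR values must be positive and finite", call. = FALSE)
  }
  for (def in definitions) {
    missing <- setdiff(def$regions, have)
    if (length(missing) > 0L) {
      stop("cohort lacks region(s) required by composite '", def$name, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    w <- def$weights / sum(def$weights)
    cohort[[def$name]] <- as.numeric(mat[, def$regions, drop = FALSE] %*% w)
  }
  cohort
}

#' Load custom composite definitions from a JSON file
#'
#' The file maps composite names to region-name arrays, e.g.
#' `{"MyROI": ["entorhinal", "amygdala"]}`. Built-in names may only be
#' overridden when `allow_override = TRUE`; silent replacement of a built-in
#' is refused.
#'
#' @param path Path to a JSON file.
#' @param allow_override Allow redefining a built-in composite name.
#' @return A registry list merging built-ins and the custom definitions.
#' @export
load_composites <- function(path, allow_override = FALSE) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  builtin <- composite_definitions()
  clash <- intersect(names(raw), names(builtin))
  if (length(clash) > 0L && !allow_override) {
    stop("custom composites would override built-in definition(s): ",
         paste(clash, collapse = ", "),
         "; pass allow_override = TRUE to do this explicitly", call. = FALSE)
  }
  custom <- purrr::imap(raw, function(regions, name) {
    new_composite(name, as.character(regions))
  })
  c(builtin[setdiff(names(builtin), names(custom))], custom)
}
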