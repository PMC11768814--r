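#' @keywords internal
"_PACKAGE"

#' Regulatory label levels
#'
#' Canonical level sets for the three regulatory label spaces: `y1` is the
#' Chinese management list (banned / restricted / unrestricted), `y2` the
#' EPA registration flag (yes / no), `y3` the EU flag (yes / no / not
#' listed). The `y1` ordering (banned, restricted, unrestricted) is the
#' fixed class-encoding order used throughout the classification harness.
#'
#' @param set One of `"y1"`, `"y2"`, `"y3"`.
#' @return Character vector of level names.
#' @export
#' @examples
#' regulatory_levels("y1")
regulatory_levels <- function(set = c("y1", "y2", "y3")) {
  set <- match.arg(set)
  switch(set,
    y1 = c("banned", "restricted", "unrestricted"),
    y2 = c("yes", "no"),
    y3 = c("yes", "no", "not_listed")
  )
}

#' The 24 toxicity indicators
#'
#' Names of the toxicity-indicator panel: 20 probability-type endpoints
#' (values in \[0, 1\], higher = more likely toxic) plus four continuous
#' ecotoxicological endpoints -- the bioconcentration factor (BCF), the
#' Tetrahymena growth-inhibition concentration (IGC50), and the median
#' lethal concentrations for Daphnia magna (LC50DM) and fathead minnow
#' (LC50FM).
#'
#' @return Character vector of length 24.
#' @seealso [default_orientation()]
#' @export
toxicity_indicator_names <- function() {
  c("hERG_blockers", "hERG_blockers_10um", "DILI", "AMES_toxicity",
    "rat_oral_acute_toxicity", "FDAMDD", "skin_sensitization",
    "carcinogenicity", "eye_corrosion", "eye_irritation",
    "respiratory_toxicity", "human_hepatotoxicity", "nephrotoxicity",
    "neurotoxicity", "ototoxicity", "nematotoxicity", "genotoxicity",
    "RPMI8226_immunotoxicity", "A549_cytotoxicity", "Hek293_cytotoxicity",
    "BCF", "IGC50", "LC50DM", "LC50FM")
}

#' Names of the probability-type indicators (the first 20 of the panel).
#' @return Character vector of length 20.
#' @export
probability_indicator_names <- function() {
  setdiff(toxicity_indicator_names(), c("BCF", "IGC50", "LC50DM", "LC50FM"))
}

#' Default indicator orientation
#'
#' Orientation of each indicator with respect to toxicity. For
#' `"benefit"` columns a larger raw value means more toxic (all
#' probability indicators and BCF, which measures bioaccumulation
#' potential). For `"cost"` columns a *smaller* raw value means more toxic
#' (IGC50, LC50DM, LC50FM: lower effective/lethal concentration = higher
#' potency), so their min-max normalization is flipped.
#'
#' @return Named character vector over [toxicity_indicator_names()], values
#'   `"benefit"` or `"cost"`.
#' @export
default_orientation <- function() {
  nm <- toxicity_indicator_names()
  o <- rep("benefit", length(nm))
  names(o) <- nm
  o[c("IGC50", "LC50DM", "LC50FM")] <- "cost"
  o
}

#' Construct a descriptor matrix
#'
#' A descriptor matrix is a plain numeric matrix (molecules in rows,
#' molecular descriptors in columns) with unique, non-empty dimnames.
#' Missing descriptor values are `NA`, never 0.
#'
#' @param values Numeric matrix or data frame.
#' @param molecule_names,descriptor_names Optional dimnames; taken from
#'   `values` when absent.
#' @return A validated numeric matrix.
#' @export
descriptor_matrix <- function(values, molecule_names = rownames(values),
                              descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- molecule_names
  colnames(values) <- descriptor_names
  validate_axis_names(rownames(values), "molecule")
  validate_axis_names(colnames(values), "descriptor")
  values
}

validate_axis_names <- function(nm, what) {
  if (is.null(nm) || any(!nzchar(nm))) {
    stop(sprintf("%s names must be present and non-empty", what),
         call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate %s name(s): %s", what,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(nm)
}

#' Construct a toxicity matrix
#'
#' Entities (parent compounds or transformation products) in rows, the 24
#' toxicity indicators in columns, plus a per-indicator orientation map
#' (see [default_orientation()]). Probability-type indicators must lie in
#' \[0, 1\]; the continuous eco-endpoints must be nonnegative.
#'
#' @param values Numeric matrix with entity rownames and indicator colnames.
#' @param orientation Named character vector (`"benefit"`/`"cost"`) over the
#'   indicator names; defaults to [default_orientation()] restricted to the
#'   columns present.
#' @return Object of class `toxicity_matrix`: list with `values` and
#'   `orientation`.
#' @export
toxicity_matrix <- function(values, orientation = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) > 0) validate_axis_names(rownames(values), "entity")
  validate_axis_names(colnames(values), "indicator")
  if (is.null(orientation)) {
    defaults <- default_orientation()
    orientation <- ifelse(colnames(values) %in% names(defaults),
                          defaults[colnames(values)], "benefit")
    names(orientation) <- colnames(values)
  }
  if (!setequal(names(orientation), colnames(values))) {
    stop("orientation must name exactly the indicator columns", call. = FALSE)
  }
  orientation <- orientation[colnames(values)]
  if (!all(orientation %in% c("benefit", "cost"))) {
    stop("orientation values must be 'benefit' or 'cost'", call. = FALSE)
  }
  prob_cols <- intersect(colnames(values), probability_indicator_names())
  pv <- values[, prob_cols, drop = FALSE]
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) {
    stop("probability-type indicators must lie in [0, 1]", call. = FALSE)
  }
  cont_cols <- intersect(colnames(values), c("BCF", "IGC50", "LC50DM", "LC50FM"))
  if (any(values[, cont_cols, drop = FALSE] < 0, na.rm = TRUE)) {
    stop("continuous eco-endpoints must be nonnegative", call. = FALSE)
  }
  structure(list(values = values, orientation = orientation),
            class = "toxicity_matrix")
}

#' @export
print.toxicity_matrix <- function(x, ...) {
  cat(sprintf("<toxicity_matrix> %d entities x %d indicators (%d cost-oriented)\n",
              nrow(x$values), ncol(x$values), sum(x$orientation == "cost")))
  invisible(x)
}

#' @export
dim.toxicity_matrix <- function(x) dim(x$values)

#' Construct a parent-to-product transformation map
#'
#' @param map Named list: parent name -> character vector of product
#'   entity names (possibly empty).
#' @return Validated named list of class `transformation_map`.
#' @export
transformation_map <- function(map) {
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    stop("every parent must be named", call. = FALSE)
  }
  if (anyDuplicated(names(map))) {
    stop("duplicate parent name(s) in transformation map", call. = FALSE)
  }
  map <- lapply(map, as.character)
  prods <- unlist(map, use.names = FALSE)
  if (anyDuplicated(prods)) {
    stop(sprintf("product(s) assigned to more than one parent: %s",
                 paste(unique(prods[duplicated(prods)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(map, class = "transformation_map")
}
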