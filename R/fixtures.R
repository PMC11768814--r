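#' Load the packaged reference tables
#'
#' Four small tables ship with the package and anchor the test suite and
#' the reproduction checks:
#'
#' * `china_list` -- the Chinese OPs management list: 79 molecules with
#'   level banned (17), restricted (8) or unrestricted (54). The source
#'   list contains two entries that are reproduced verbatim rather than
#'   repaired: "Mecarbam" appears twice among the unrestricted molecules,
#'   and "Phosphoric acid" is listed as a banned pesticide.
#' * `importance_table` -- 78 retained molecular descriptors with their
#'   random-forest importance share and min-max relative importance.
#' * `application_predictions` -- predicted Chinese regulatory status for
#'   170 OPs molecules registered in the EU but absent from the Chinese
#'   list (labels Banned / Restricted / Unrestricted).
#' * `composite_toxicity` -- composite toxicity score and published
#'   attention level for the 54 unrestricted-class molecules.
#'
#' Shapes and tallies are validated on load; a mismatch is an error
#' (the fixtures are bit-exact data, not code).
#'
#' @return Named list with the four data frames.
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' table(fx$china_list$level)
load_paper_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "opswatch")
    if (!nzchar(p)) stop("missing packaged fixture: ", f, call. = FALSE)
    p
  }
  china <- utils::read.csv(path("table1_china_list.csv"))
  imp <- utils::read.csv(path("table3_importance.csv"))
  app <- utils::read.csv(path("table5_predictions.csv"))
  comp <- utils::read.csv(path("table6_composite_toxicity.csv"))

  check <- function(ok, msg) if (!ok) stop("fixture corrupted: ", msg, call. = FALSE)
  check(nrow(china) == 79, "china_list must have 79 rows")
  tl <- table(factor(china$level, levels = regulatory_levels("y1")))
  check(all(tl == c(banned = 17, restricted = 8, unrestricted = 54)),
        "china_list tallies must be 17/8/54")
  check(nrow(imp) == 78 && !anyDuplicated(imp$descriptor),
        "importance_table must have 78 unique descriptors")
  check(all(imp$importance >= 0) &&
          all(imp$relative_importance >= 0 & imp$relative_importance <= 1),
        "importance_table values out of range")
  check(nrow(app) == 170 && !anyDuplicated(app$name),
        "application_predictions must have 170 unique molecules")
  check(all(app$prediction %in% c("Banned", "Restricted", "Unrestricted")),
        "application_predictions labels out of range")
  check(nrow(comp) == 54 && !anyDuplicated(comp$name),
        "composite_toxicity must have 54 unique molecules")
  check(all(comp$composite_toxicity > 0 & comp$composite_toxicity < 1),
        "composite toxicity scores must lie in (0, 1)")

  list(china_list = china, importance_table = imp,
       application_predictions = app, composite_toxicity = comp)
}

#' Map printed prediction labels onto the y1 enum
#'
#' The application table prints "Banned"/"Restricted"/"Unrestricted";
#' downstream code uses the lowercase y1 levels.
#'
#' @param labels Character vector of printed labels.
#' @return Factor over [regulatory_levels()]`("y1")`.
#' @export
printed_to_y1 <- function(labels) {
  map <- c(Banned = "banned", Restricted = "restricted",
           Unrestricted = "unrestricted")
  bad <- setdiff(unique(labels), names(map))
  if (length(bad)) stop("unknown printed label(s): ", paste(bad, collapse = ", "))
  factor(unname(map[labels]), levels = regulatory_levels("y1"))
}
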