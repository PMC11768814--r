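#' Attention levels, highest priority first
#'
#' Internal codes and the corresponding published labels: `special` =
#' "Special Focus", `focus` = "Focus", `general` = "General Focus",
#' `secondary` = "Secondary Focus".
#'
#' @return Character vector of the four level codes.
#' @export
attention_levels <- function() c("special", "focus", "general", "secondary")

#' @rdname attention_levels
#' @param levels Level codes to translate.
#' @return `attention_labels`: the published label for each code.
#' @export
attention_labels <- function(levels = attention_levels()) {
  map <- c(special = "Special Focus", focus = "Focus",
           general = "General Focus", secondary = "Secondary Focus")
  unname(map[as.character(levels)])
}

#' Mean and dispersion of composite toxicity scores
#'
#' The interval width for the watch list is based on the population
#' standard deviation (divisor n) of the composite scores.
#'
#' @param scores Numeric vector of composite toxicity scores (>= 2).
#' @return List with `mean` and `delta` (population SD).
#' @export
compute_delta <- function(scores) {
  if (length(scores) < 2 || anyNA(scores)) {
    stop("need >= 2 non-missing scores", call. = FALSE)
  }
  m <- mean(scores)
  list(mean = m, delta = sqrt(mean((scores - m)^2)))
}

#' Assign attention levels by standard-deviation intervals
#'
#' Bins each score's deviation from the mean, `d = C - mean`, into four
#' left-open/right-closed intervals of width `1.85 * delta`:
#' special `(1.85d, 3.7d]`, focus `(0, 1.85d]`, general `(-1.85d, 0]`,
#' secondary `(-3.7d, -1.85d]` -- so a score exactly at the mean falls in
#' "general", and a higher score never gets a lower-priority level.
#' Deviations beyond +/- 3.7 delta clamp to the nearest extreme level
#' with a warning.
#'
#' @param scores Named numeric vector of composite toxicity scores.
#' @param center,delta Optional precomputed mean and dispersion; by
#'   default recomputed from `scores` via [compute_delta()].
#' @return Data frame of class `ops_watchlist` with columns `name`,
#'   `composite_toxicity`, `deviation`, `level` (factor over
#'   [attention_levels()]), sorted by score descending (ties by name);
#'   attributes `mean` and `delta`.
#' @export
assign_levels <- function(scores, center = NULL, delta = NULL) {
  validate_axis_names(names(scores), "molecule")
  if (is.null(center) || is.null(delta)) {
    md <- compute_delta(scores)
    if (is.null(center)) center <- md$mean
    if (is.null(delta)) delta <- md$delta
  }
  if (delta <= 0) stop("no dispersion; levels undefined", call. = FALSE)
  d <- scores - center
  if (any(d > 3.7 * delta) || any(d <= -3.7 * delta)) {
    warning("score(s) beyond +/-3.7 delta clamped to the extreme level",
            call. = FALSE)
  }
  lev <- ifelse(d > 1.85 * delta, "special",
         ifelse(d > 0, "focus",
         ifelse(d > -1.85 * delta, "general", "secondary")))
  out <- data.frame(name = names(scores),
                    composite_toxicity = unname(scores),
                    deviation = unname(d),
                    level = factor(lev, levels = attention_levels()))
  out <- out[order(-out$composite_toxicity, out$name), ]
  rownames(out) <- NULL
  attr(out, "mean") <- center
  attr(out, "delta") <- delta
  class(out) <- c("ops_watchlist", "data.frame")
  out
}

#' Full watch-list pipeline from raw toxicity tables
#'
#' Convenience wrapper: [score_composite_toxicity()] then
#' [assign_levels()] on the TOPSIS closeness scores.
#'
#' @inheritParams score_composite_toxicity
#' @return List with `scores` (the [score_composite_toxicity()] output)
#'   and `watchlist` (an `ops_watchlist`).
#' @export
build_watchlist <- function(parents, products = NULL, map = NULL,
                            parent_weight = 0.5) {
  sc <- score_composite_toxicity(parents, products, map, parent_weight)
  scores <- stats::setNames(sc$mcda$closeness, sc$mcda$name)
  list(scores = sc, watchlist = assign_levels(scores))
}

#' Re-run every published-table reproduction check
#'
#' Recomputes, from the packaged fixtures alone: the management-list
#' tallies (17/8/54), the application-prediction tally (75/6/89 over
#' 170), the dispersion of the 54 composite toxicity scores
#' (delta = 0.0459 within input-rounding tolerance), the 54/54 agreement
#' of the mean-centered 1.85-delta binning with the published attention
#' levels, and the min-max recomputation of all 78 relative importances
#' (within +/-0.005). Emits a pass/fail report.
#'
#' @param out Optional path; when given, the report is written as JSON.
#' @param stop_on_failure Raise an error naming the failed checks.
#' @return List of class `ops_report`: per-check `pass` flag plus
#'   measured values, and an overall `pass`.
#' @export
reproduce_paper <- function(out = NULL, stop_on_failure = FALSE) {
  fx <- load_paper_fixtures()

  tl <- tally_labels(fx$china_list$level)
  chk_china <- list(observed = as.list(tl),
                    pass = all(tl == c(17L, 8L, 54L)))

  tally <- tally_labels(printed_to_y1(fx$application_predictions$prediction))
  chk_tally <- list(observed = as.list(tally), n = nrow(fx$application_predictions),
                    pass = all(tally == c(75L, 6L, 89L)))

  md <- compute_delta(fx$composite_toxicity$composite_toxicity)
  chk_delta <- list(delta = md$delta, reference = 0.0459,
                    pass = abs(md$delta - 0.0459) <= 5e-4)

  wl <- assign_levels(stats::setNames(fx$composite_toxicity$composite_toxicity,
                                      fx$composite_toxicity$name))
  printed <- stats::setNames(fx$composite_toxicity$printed_level,
                             fx$composite_toxicity$name)
  agree <- sum(attention_labels(wl$level) == printed[wl$name])
  chk_levels <- list(agreement = agree, n = nrow(wl), pass = agree == nrow(wl))

  rel <- relative_importance(fx$importance_table[c("descriptor", "importance")])
  err <- max(abs(rel$relative_importance - fx$importance_table$relative_importance))
  chk_rel <- list(max_abs_error = err, pass = err <= 0.005)

  checks <- list(china_list_tallies = chk_china,
                 application_tally = chk_tally,
                 delta_recomputation = chk_delta,
                 watchlist_agreement = chk_levels,
                 relative_importance = chk_rel)
  report <- structure(list(checks = checks,
                           pass = all(vapply(checks, `[[`, logical(1), "pass"))),
                      class = "ops_report")
  if (!is.null(out)) {
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA)
  }
  if (stop_on_failure && !report$pass) {
    failed <- names(checks)[!vapply(checks, `[[`, logical(1), "pass")]
    stop("reproduction check(s) failed: ", paste(failed, collapse = ", "),
         call. = FALSE)
  }
  report
}

#' @export
print.ops_report <- function(x, ...) {
  for (nm in names(x$checks)) {
    cat(sprintf("%-24s %s\n", nm, if (x$checks[[nm]]$pass) "PASS" else "FAIL"))
  }
  cat("overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
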