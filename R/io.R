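#' Read a descriptor table from CSV
#'
#' Expects a header row, the first column holding molecule names and the
#' remaining columns numeric descriptors. Empty cells and the literal
#' strings `NA`/`na`/`N/A` are canonicalized to missing (`NA`), never to 0.
#' Column order is preserved.
#'
#' @param path Path to a CSV file (UTF-8, comma-delimited, "." decimal).
#' @return A descriptor matrix (see [descriptor_matrix()]).
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character())
  if (ncol(df) < 2) stop("descriptor table needs a name column plus >= 1 descriptor")
  validate_axis_names(df[[1]], "molecule")
  validate_axis_names(colnames(df)[-1], "descriptor")
  vals <- vapply(seq_len(ncol(df) - 1L), function(j) {
    col <- trimws(df[[j + 1L]])
    miss <- col %in% c("", "NA", "na", "N/A")
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out) & !miss)
    if (length(bad)) {
      stop(sprintf("non-numeric value %s at row %d, column %s",
                   dQuote(col[bad[1]]), bad[1], dQuote(colnames(df)[j + 1L])),
           call. = FALSE)
    }
    out
  }, numeric(nrow(df)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(df))
  descriptor_matrix(vals, molecule_names = df[[1]],
                    descriptor_names = colnames(df)[-1])
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; missing values are written as
#' empty cells.
#'
#' @param x Descriptor matrix.
#' @param path Output path.
#' @export
write_descriptor_table <- function(x, path) {
  df <- data.frame(name = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a toxicity-indicator table from CSV
#'
#' Same dialect as [read_descriptor_table()]; the column set must be a
#' subset of [toxicity_indicator_names()] unless `strict = FALSE`.
#'
#' @param path Path to a CSV file.
#' @param orientation Optional orientation map; defaults per
#'   [default_orientation()].
#' @param strict Require the full canonical 24-indicator panel.
#' @return A [toxicity_matrix()].
#' @export
read_toxicity_table <- function(path, orientation = NULL, strict = TRUE) {
  m <- read_descriptor_table(path)
  if (strict && !setequal(colnames(m), toxicity_indicator_names())) {
    stop("toxicity table must carry exactly the 24 canonical indicators",
         call. = FALSE)
  }
  toxicity_matrix(m, orientation = orientation)
}

#' Write a toxicity-indicator table to CSV
#' @param x A `toxicity_matrix`.
#' @param path Output path.
#' @export
write_toxicity_table <- function(x, path) {
  write_descriptor_table(x$values, path)
}

#' Read / write a transformation map as JSON
#'
#' The map is stored as a JSON object: parent name -> array of product
#' names.
#'
#' @param path File path.
#' @return `read_transformation_map` returns a [transformation_map()].
#' @export
read_transformation_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(v) if (is.null(v)) character() else as.character(v))
  transformation_map(raw)
}

#' @rdname read_transformation_map
#' @param map A `transformation_map`.
#' @export
write_transformation_map <- function(map, path) {
  jsonlite::write_json(lapply(unclass(map), I), path, auto_unbox = FALSE)
  invisible(path)
}

#' Write a watch list to CSV
#'
#' Columns `name`, `composite_toxicity`, `deviation`, `level`, sorted by
#' composite toxicity descending with ties broken by name ascending.
#'
#' @param wl Watch list from [assign_levels()] (or any data frame with the
#'   four columns).
#' @param path Output path.
#' @export
write_watchlist <- function(wl, path) {
  cols <- c("name", "composite_toxicity", "deviation", "level")
  if (!all(cols %in% names(wl))) {
    stop("watch list must have columns ", paste(cols, collapse = ", "))
  }
  wl <- wl[order(-wl$composite_toxicity, wl$name), cols]
  utils::write.csv(wl, path, row.names = FALSE)
  invisible(path)
}

#' Read a watch list written by [write_watchlist()]
#' @param path CSV path.
#' @return Data frame with the four watch-list columns.
#' @export
read_watchlist <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$level <- factor(df$level, levels = attention_levels())
  df
}
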