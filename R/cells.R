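#' Single-cell slide tables
#'
#' A cell table is the package's input data structure: one row per cell
#' segmented from a whole-slide H&E image, with planar centroid
#' coordinates in micrometres (image convention: origin at the slide's
#' top-left corner, y increasing downward), a cell class (`cancer`,
#' `stromal` or `lymphocyte`), and the nuclear area (um^2) and perimeter
#' (um) from which the nuclear shape factor is derived. An optional
#' `marker_value` column carries a per-cell marker score (e.g. IHC
#' positivity) for zone-level marker analyses.
#'
#' `cell_table()` validates a data frame and stamps it as a cell table;
#' it is the constructor used by the readers and the simulator.
#'
#' @param cells data frame with columns `cell_id`, `x`, `y`,
#'   `cell_class`, `nucleus_area`, `nucleus_perimeter` and optionally
#'   `marker_value`.
#' @param slide_id identifier of the slide the cells came from.
#' @return A data frame of class `cell_table` with attributes
#'   `slide_id` and `units` (always `"um"`).
#' @examples
#' tab <- cell_table(data.frame(
#'   cell_id = 1:3, x = c(0, 10, 20), y = c(0, 5, 2),
#'   cell_class = c("cancer", "cancer", "lymphocyte"),
#'   nucleus_area = c(40, 38, 12), nucleus_perimeter = c(25, 24, 13)),
#'   slide_id = "demo")
#' validate_cell_table(tab)
#' @seealso [read_cell_table()], [validate_cell_table()]
#' @export
cell_table <- function(cells, slide_id = "slide") {
  required <- c("cell_id", "x", "y", "cell_class",
                "nucleus_area", "nucleus_perimeter")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- c(required, intersect("marker_value", names(cells)))
  cells <- as.data.frame(cells)[, keep]
  for (col in c("x", "y", "nucleus_area", "nucleus_perimeter"))
    cells[[col]] <- as.numeric(cells[[col]])
  cells$cell_class <- as.character(cells$cell_class)
  rownames(cells) <- NULL
  structure(cells, slide_id = as.character(slide_id), units = "um",
            class = c("cell_table", "data.frame"))
}

#' @rdname cell_table
#' @param x object to test.
#' @export
is_cell_table <- function(x) inherits(x, "cell_table")

#' Slide identifier of a cell table or zone map
#'
#' @param x a `cell_table`, `zone_map` or `morphozone` object.
#' @return character slide identifier.
#' @export
slide_id <- function(x) attr(x, "slide_id", exact = TRUE) %||% x$slide_id

`%||%` <- function(a, b) if (is.null(a)) b else a

.known_classes <- c("cancer", "stromal", "lymphocyte")

#' Read a cell table from delimited text
#'
#' Reads a CSV of per-cell measurements into a [cell_table()]. Column
#' names can be remapped for files produced by other image-analysis
#' pipelines, either with a named character vector (canonical name ->
#' file column name) or with a YAML config file containing a `columns:`
#' mapping and optionally `slide_id:` and `coordinate_scale:` (a factor
#' multiplying x and y, e.g. 0.5 for centroids exported in pixels at
#' 0.5 um/pixel).
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping canonical column names
#'   to the file's column names, or the path to a YAML config file.
#' @param slide_id slide identifier; defaults to the file name.
#' @param sep field separator.
#' @return a [cell_table()]. Row order of the file is preserved.
#' @export
read_cell_table <- function(path, columns = NULL, slide_id = NULL, sep = ",") {
  coord_scale <- 1
  if (is.character(columns) && length(columns) == 1L && file.exists(columns) &&
      is.null(names(columns))) {
    cfg <- yaml::read_yaml(columns)
    columns <- unlist(cfg$columns)
    # YAML 1.1 parses bare y/n keys as booleans; map them back
    names(columns)[names(columns) == "TRUE"] <- "y"
    names(columns)[names(columns) == "FALSE"] <- "n"
    if (!is.null(cfg$slide_id) && is.null(slide_id)) slide_id <- cfg$slide_id
    if (!is.null(cfg$coordinate_scale)) coord_scale <- cfg$coordinate_scale
  }
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         comment.char = "#", check.names = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      src <- columns[[canon]]
      if (!src %in% names(raw))
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  required <- c("cell_id", "x", "y", "cell_class",
                "nucleus_area", "nucleus_perimeter")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", "nucleus_area", "nucleus_perimeter")) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals) & trimws(as.character(vals)) != "")
    if (length(bad))
      stop("column '", col, "' of ", path, " is not numeric at data line(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    raw[[col]] <- num
  }
  raw$x <- raw$x * coord_scale
  raw$y <- raw$y * coord_scale
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]*$", "", basename(path))
  cell_table(raw, slide_id = slide_id)
}

#' Write a cell table to CSV
#'
#' Writes the canonical column order at full double precision so that
#' `read_cell_table()` reproduces the table exactly.
#'
#' @param table a [cell_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  stopifnot(is_cell_table(table))
  out <- as.data.frame(table)
  for (col in names(out))
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cell table
#'
#' Reports, without raising, every rule violation in a cell table:
#' non-positive nuclear area or perimeter, duplicated cell ids, cell
#' classes outside `cancer`/`stromal`/`lymphocyte`, and non-finite
#' coordinates. A clean table yields a zero-row report.
#'
#' @param table a [cell_table()] (or any data frame with its columns).
#' @return data frame with columns `row`, `field`, `message`; zero rows
#'   if the table is valid.
#' @export
validate_cell_table <- function(table) {
  rows <- integer(); fields <- character(); msgs <- character()
  note <- function(r, f, m) {
    rows <<- c(rows, r); fields <<- c(fields, f); msgs <<- c(msgs, m)
  }
  bad <- which(!is.finite(table$nucleus_area) | table$nucleus_area <= 0)
  for (r in bad) note(r, "nucleus_area", "nucleus_area must be positive")
  bad <- which(!is.finite(table$nucleus_perimeter) | table$nucleus_perimeter <= 0)
  for (r in bad) note(r, "nucleus_perimeter", "nucleus_perimeter must be positive")
  bad <- which(duplicated(table$cell_id))
  for (r in bad) note(r, "cell_id", paste0("duplicate cell_id '", table$cell_id[r], "'"))
  bad <- which(!table$cell_class %in% .known_classes)
  for (r in bad) note(r, "cell_class",
                      paste0("unknown cell_class '", table$cell_class[r], "'"))
  bad <- which(!is.finite(table$x) | !is.finite(table$y))
  for (r in bad) note(r, "x/y", "coordinates must be finite")
  data.frame(row = rows, field = fields, message = msgs,
             stringsAsFactors = FALSE)
}

#' @export
print.cell_table <- function(x, ...) {
  cat("Cell table '", slide_id(x), "': ", nrow(x), " cells (",
      sum(x$cell_class == "cancer"), " cancer, ",
      sum(x$cell_class == "lymphocyte"), " lymphocyte, ",
      sum(x$cell_class == "stromal"), " stromal); units: um\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
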