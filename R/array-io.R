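# Reading and writing the simplified GenePix ATF/GPR dialect and the
# experiment design table.

# Exact column-header row of the dialect, in order.
.gpr_columns <- c("Block", "Column", "Row", "Name", "ID", "Dia.",
                  "F635 Median", "B635 Median", "F532 Median", "B532 Median",
                  "Flags")

# internal data.frame column names, parallel to .gpr_columns
.spot_columns <- c("block", "column", "row", "name", "gene_id", "diameter_um",
                   "f635", "b635", "f532", "b532", "flags")

.numeric_spot_columns <- c("block", "column", "row", "diameter_um",
                           "f635", "b635", "f532", "b532", "flags")

#' Construct a single-hybridization array scan
#'
#' An `array_scan` bundles one array's spot-level quantification with the
#' metadata needed to interpret it: which comparison it belongs to and the
#' dye orientation.  In `"forward"` orientation the test sample is Cy5-labeled
#' (635 nm channel) and the reference Cy3-labeled (532 nm); `"swapped"`
#' reverses the roles.
#'
#' @param array_id Character scalar identifying the hybridization.
#' @param comparison_id Character scalar naming the biological comparison
#'   (test vs reference) this array measures.
#' @param orientation `"forward"` or `"swapped"`.
#' @param spots A data.frame with one row per spot and columns `block`,
#'   `column`, `row` (1-based grid indices), `name`, `gene_id` (systematic
#'   name, or `"EMPTY"`/blank for control spots), `diameter_um`, `f635`,
#'   `b635`, `f532`, `b532` (foreground/background medians per channel) and
#'   `flags` (negative = manually flagged bad).
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(array_id, comparison_id, orientation, spots) {
  orientation <- match.arg(orientation, c("forward", "swapped"))
  stopifnot(is.character(array_id), length(array_id) == 1L,
            is.character(comparison_id), length(comparison_id) == 1L,
            is.data.frame(spots))
  missing_cols <- setdiff(.spot_columns, names(spots))
  if (length(missing_cols) > 0L)
    stop("spot table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(spots) < 1L)
    stop("an array_scan must contain at least one spot")
  if (any(spots$diameter_um <= 0))
    stop("spot diameters must be positive")
  int_cols <- c("f635", "b635", "f532", "b532")
  if (any(as.matrix(spots[int_cols]) < 0))
    stop("intensities must be non-negative")
  key <- paste(spots$block, spots$column, spots$row)
  if (anyDuplicated(key))
    stop("duplicate (block, column, row) grid position in spot table")
  structure(
    list(array_id = array_id, comparison_id = comparison_id,
         orientation = orientation,
         spots = spots[.spot_columns]),
    class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan %s (comparison %s, %s): %d spots\n",
              x$array_id, x$comparison_id, x$orientation, nrow(x$spots)))
  invisible(x)
}

.fmt1 <- function(x) sprintf("%.1f", x)

#' Write an array scan as a GPR file
#'
#' Emits the simplified ATF dialect: `ATF<TAB>1.0`, a record-count line, three
#' `Key=Value` header records (`ArrayID`, `ComparisonID`, `Orientation`), the
#' column-header row and one tab-separated row per spot.  Output is
#' byte-stable for a given scan: fixed column order and 1-decimal formatting
#' for diameters and intensities.
#'
#' @param scan An [array_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  s <- scan$spots
  header <- c("ATF\t1.0",
              "3\t11",
              paste0("ArrayID=", scan$array_id),
              paste0("ComparisonID=", scan$comparison_id),
              paste0("Orientation=", scan$orientation),
              paste(.gpr_columns, collapse = "\t"))
  rows <- paste(s$block, s$column, s$row, s$name, s$gene_id,
                .fmt1(s$diameter_um),
                .fmt1(s$f635), .fmt1(s$b635), .fmt1(s$f532), .fmt1(s$b532),
                s$flags, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a GPR file into an array scan
#'
#' Parses the dialect written by [write_gpr()].  The parser accepts LF or
#' CRLF line endings and ignores trailing blank lines.  Mandatory columns and
#' numeric fields are validated with informative errors.
#'
#' @param path Path to a GPR file.
#' @return An [array_scan()].
#' @export
read_gpr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) < 4L || !identical(strsplit(lines[1L], "\t")[[1L]][1L], "ATF"))
    stop("not an ATF file: ", path)
  counts <- strsplit(lines[2L], "\t")[[1L]]
  n_header <- as.integer(counts[1L])
  if (is.na(n_header) || length(lines) < 2L + n_header + 1L)
    stop("malformed ATF record-count line in ", path)
  meta <- lines[3L:(2L + n_header)]
  kv <- strsplit(meta, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
  names(vals) <- keys
  for (k in c("ArrayID", "ComparisonID", "Orientation"))
    if (!k %in% keys) stop("missing header record: ", k)
  header_line <- 2L + n_header + 1L
  cols <- strsplit(lines[header_line], "\t")[[1L]]
  for (k in .gpr_columns)
    if (!k %in% cols) stop("missing mandatory column: ", k)
  data_lines <- lines[seq.int(header_line + 1L, length(lines))]
  if (header_line >= length(lines)) stop("GPR file has no data rows: ", path)
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  idx <- match(.gpr_columns, cols)
  get_col <- function(j) vapply(fields, function(f) {
    if (length(f) < j) "" else f[j]
  }, "")
  spots <- data.frame(matrix(nrow = length(fields), ncol = 0L))
  for (i in seq_along(.gpr_columns)) {
    raw <- get_col(idx[i])
    col <- .spot_columns[i]
    if (col %in% .numeric_spot_columns) {
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val)) {
        bad <- which(is.na(val))[1L]
        stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                     raw[bad], .gpr_columns[i], header_line + bad))
      }
      spots[[col]] <- val
    } else {
      spots[[col]] <- raw
    }
  }
  spots$block <- as.integer(spots$block)
  spots$column <- as.integer(spots$column)
  spots$row <- as.integer(spots$row)
  spots$flags <- as.integer(spots$flags)
  array_scan(array_id = unname(vals[["ArrayID"]]),
             comparison_id = unname(vals[["ComparisonID"]]),
             orientation = unname(vals[["Orientation"]]),
             spots = spots)
}

#' Read and validate an experiment design table
#'
#' The design table is a TSV with header columns `comparison_id`, `array_id`,
#' `orientation`, `path`, `strain`, `condition`.  Every comparison must have
#' exactly one `forward` and one `swapped` array (a dye-swap technical
#' replica pair).
#'
#' @param path Path to the design TSV.
#' @return A data.frame of class `design_table`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("comparison_id", "array_id", "orientation", "path",
                "strain", "condition")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L)
    stop("design table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_orient <- setdiff(unique(d$orientation), c("forward", "swapped"))
  if (length(bad_orient) > 0L)
    stop("unknown orientation token(s): ", paste(bad_orient, collapse = ", "))
  as_design_table(d[required])
}

#' Validate a data.frame as a design table
#'
#' @param d A data.frame with the design-table columns.
#' @return `d` with class `design_table` prepended.
#' @export
as_design_table <- function(d) {
  bad <- character()
  for (cmp in unique(d$comparison_id)) {
    sub <- d[d$comparison_id == cmp, ]
    if (sum(sub$orientation == "forward") != 1L ||
        sum(sub$orientation == "swapped") != 1L)
      bad <- c(bad, cmp)
  }
  if (length(bad) > 0L)
    stop("design error: comparison(s) without exactly one forward and one ",
         "swapped array: ", paste(bad, collapse = ", "))
  class(d) <- c("design_table", class(d))
  d
}

#' Write a design table as TSV
#'
#' @param design A `design_table` (or conforming data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
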