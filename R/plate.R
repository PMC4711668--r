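PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12
WELL_ROLES <- c("positive", "negative", "sample", "blank")
DETECTION_MODES <- c("absorbance", "luminescence")

#' Canonical 96-well labels in row-major order
#'
#' Row-major means A1, A2, ..., A12, B1, ..., H12.  This ordering is the
#' package-wide convention: control extraction and plate simulation both
#' follow it, so the two operations are mutual inverses.
#'
#' @return Character vector of the 96 canonical well labels.
#' @export
well_labels <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' Parse a 96-well plate well label
#'
#' Accepts labels of the form letter + column, e.g. `"A1"` or `"H12"`.
#' Only the 96-well geometry (rows A-H, columns 1-12) is supported;
#' 384- and 1536-well labels are rejected at parse time.
#'
#' @param label A single well label such as `"B7"`.
#' @return An object of class `well_address` with fields `row` (letter)
#'   and `column` (integer).  `format()` restores the label.
#' @examples
#' w <- parse_well_label("H12")
#' w$row
#' w$column
#' format(w)
#' @export
parse_well_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    input_error("well label must be a single character string")
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]{1,2})$", label))[[1]]
  if (length(m) == 0L)
    input_error(sprintf("malformed well label '%s'", label))
  row <- toupper(m[2])
  column <- as.integer(m[3])
  if (!(row %in% PLATE_ROWS) || !(column %in% PLATE_COLS))
    input_error(sprintf(
      "well label '%s' outside the 96-well geometry (rows A-H, columns 1-12)",
      label))
  structure(list(row = row, column = column), class = "well_address")
}

#' @export
format.well_address <- function(x, ...) paste0(x$row, x$column)

#' @export
print.well_address <- function(x, ...) {
  cat("well", format(x), sprintf("(row %s, column %d)\n", x$row, x$column))
  invisible(x)
}

## Row-major index (A1 = 1 ... H12 = 96) used for deterministic ordering.
well_order_index <- function(labels) {
  match(labels, well_labels())
}

check_wells <- function(wells) {
  idx <- well_order_index(wells)
  if (anyNA(idx)) {
    bad <- unique(wells[is.na(idx)])
    ## validate individually so the error names the offending label
    for (w in bad) parse_well_label(w)
  }
  idx
}

#' Construct a plate assay
#'
#' The central data container: one plate of wells, each carrying a role
#' (positive, negative, sample or blank) and one or more measurements.
#' An *endpoint* plate has exactly one measurement per well and no time
#' stamps; a *kinetic* plate carries a time series per well (times in
#' minutes).  Values are unitless readouts (absorbance AU or
#' luminescence counts) -- units are metadata, never converted.
#'
#' @param data Data frame with columns `well`, `role`, `value` and
#'   optionally `time` (minutes; `NA` for endpoint readings).
#' @param assay_id Identifier for the assay/plate.
#' @param detection `"absorbance"` or `"luminescence"`.
#' @return An object of class `plate_assay`.
#' @export
plate_assay <- function(data, assay_id = "assay", detection = "absorbance") {
  if (!is.data.frame(data))
    input_error("'data' must be a data frame")
  needed <- c("well", "role", "value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    input_error(paste0("plate data lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  if (is.null(data$time)) data$time <- NA_real_
  detection <- match.arg(detection, DETECTION_MODES)
  data$well <- as.character(data$well)
  data$role <- as.character(data$role)
  data$time <- as.numeric(data$time)
  data$value <- as.numeric(data$value)

  check_wells(data$well)
  bad_role <- setdiff(unique(data$role), WELL_ROLES)
  if (length(bad_role))
    input_error(sprintf("unknown role '%s'; allowed roles: %s",
                        bad_role[1], paste(WELL_ROLES, collapse = ", ")))
  if (any(!is.finite(data$value)))
    input_error("non-numeric or non-finite measurement value")
  if (any(!is.na(data$time) & (data$time < 0 | !is.finite(data$time))))
    input_error("measurement times must be finite and >= 0 minutes")

  ## one role per well
  roles_per_well <- tapply(data$role, data$well, function(r) length(unique(r)))
  if (any(roles_per_well > 1L))
    input_error(sprintf("well %s is assigned more than one role",
                        names(roles_per_well)[roles_per_well > 1L][1]))
  key <- paste(data$well, data$time)
  if (anyDuplicated(key))
    input_error(sprintf("duplicate (well, time) measurement for well %s",
                        data$well[duplicated(key)][1]))

  ## row-major well order, time-sorted within well
  ord <- order(well_order_index(data$well), data$time, na.last = TRUE)
  data <- data[ord, c("well", "role", "time", "value"), drop = FALSE]
  rownames(data) <- NULL
  structure(list(assay_id = as.character(assay_id)[1],
                 detection = detection,
                 data = data),
            class = "plate_assay")
}

#' @export
print.plate_assay <- function(x, ...) {
  n_wells <- length(unique(x$data$well))
  cat(sprintf("plate assay '%s' (%s): %d wells, %d measurements\n",
              x$assay_id, x$detection, n_wells, nrow(x$data)))
  tab <- table(x$data$role[!duplicated(x$data$well)])
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (!is_endpoint(x)) cat("  kinetic plate (time series per well)\n")
  invisible(x)
}

#' @rdname plate_assay
#' @param x A `plate_assay`.
#' @export
is_endpoint <- function(x) {
  stopifnot(inherits(x, "plate_assay"))
  all(is.na(x$data$time)) && !anyDuplicated(x$data$well)
}

#' Read a plate from an 8 x 12 grid CSV
#'
#' The grid dialect mirrors how plate readers lay plates out: the first
#' column holds the row letters A-H and the header row the column
#' numbers 1-12.  Empty cells mean "well not measured" (a zero readout
#' is a legitimate value and must be written as `0`).
#'
#' @param path Path to the grid CSV.
#' @param role_map Either a named character vector mapping well labels
#'   to roles (`c(A1 = "positive", ...)`) or a data frame with columns
#'   `well` and `role`.  Every non-empty well must be covered.
#' @inheritParams plate_assay
#' @return A `plate_assay` with one endpoint measurement per non-empty
#'   cell.
#' @export
read_plate_grid <- function(path, role_map, assay_id = "assay",
                            detection = "absorbance") {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) != 8L || ncol(raw) != 13L)
    input_error(sprintf(
      "grid in %s must be 8 rows x 12 value columns (got %d x %d)",
      path, nrow(raw), ncol(raw) - 1L))
  row_letters <- toupper(trimws(raw[[1]]))
  if (!identical(row_letters, PLATE_ROWS))
    input_error("grid row labels must be A-H in order")
  col_headers <- suppressWarnings(as.integer(names(raw)[-1]))
  if (!identical(col_headers, PLATE_COLS))
    input_error("grid column headers must be 1-12 in order")

  role_map <- as_role_map(role_map)
  rows <- list()
  for (i in seq_len(8L)) {
    for (j in seq_len(12L)) {
      cell <- trimws(raw[i, j + 1L])
      if (is.na(cell) || cell == "") next
      value <- suppressWarnings(as.numeric(cell))
      well <- paste0(PLATE_ROWS[i], j)
      if (is.na(value))
        input_error(sprintf("non-numeric cell '%s' at well %s", cell, well))
      role <- role_map[well]
      if (is.na(role))
        input_error(sprintf("well %s has a value but no role in role_map",
                            well))
      rows[[length(rows) + 1L]] <-
        data.frame(well = well, role = unname(role), value = value)
    }
  }
  if (!length(rows)) input_error(sprintf("grid in %s holds no values", path))
  plate_assay(do.call(rbind, rows), assay_id = assay_id,
              detection = detection)
}

as_role_map <- function(role_map) {
  if (is.data.frame(role_map)) {
    if (!all(c("well", "role") %in% names(role_map)))
      input_error("role_map data frame needs columns 'well' and 'role'")
    out <- as.character(role_map$role)
    names(out) <- as.character(role_map$well)
    role_map <- out
  }
  if (is.null(names(role_map)) || !is.character(role_map))
    input_error("role_map must be a named character vector or data frame")
  bad <- setdiff(unique(role_map), WELL_ROLES)
  if (length(bad))
    input_error(sprintf("unknown role '%s'; allowed roles: %s", bad[1],
                        paste(WELL_ROLES, collapse = ", ")))
  role_map
}

#' Read a plate from the long CSV dialect
#'
#' Long format has header `well,role,time,value` (the `time` column may
#' be absent or blank throughout for endpoint plates).  Rows are grouped
#' by well and sorted by time.
#'
#' @inheritParams read_plate_grid
#' @return A `plate_assay`.
#' @export
read_long_format <- function(path, assay_id = NULL,
                             detection = "absorbance") {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("well", "role", "value") %in% names(raw)))
    input_error(sprintf("%s must have columns well, role, value", path))
  if (is.null(assay_id))
    assay_id <- sub("\\.csv$", "", basename(path))
  plate_assay(raw, assay_id = assay_id, detection = detection)
}

#' Write a plate in the long CSV dialect
#'
#' @param plate A `plate_assay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_format <- function(plate, path) {
  stopifnot(inherits(plate, "plate_assay"))
  utils::write.csv(plate$data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Paired positive/negative control readouts
#'
#' @param pos,neg Numeric vectors of positive- and negative-control
#'   endpoint readouts.
#' @return An object of class `control_groups`.
#' @export
control_groups <- function(pos, neg) {
  pos <- as.numeric(pos); neg <- as.numeric(neg)
  if (!length(pos)) input_error("positive-control vector is empty")
  if (!length(neg)) input_error("negative-control vector is empty")
  if (any(!is.finite(pos)) || any(!is.finite(neg)))
    input_error("control readouts must all be finite")
  structure(list(pos = pos, neg = neg), class = "control_groups")
}

#' @export
print.control_groups <- function(x, ...) {
  cat(sprintf("control groups: %d positives (mean %.4g), %d negatives (mean %.4g)\n",
              length(x$pos), mean(x$pos), length(x$neg), mean(x$neg)))
  invisible(x)
}

#' Extract control readouts from an endpoint plate
#'
#' Returns the endpoint values of the positive- and negative-control
#' wells in row-major well order (A1 ... H12), the package's canonical
#' ordering, so the extraction is deterministic and inverts
#' [simulate_control_plate()].
#'
#' @param plate An endpoint `plate_assay` with at least one positive and
#'   one negative well.
#' @return A `control_groups` object.
#' @export
extract_controls <- function(plate) {
  stopifnot(inherits(plate, "plate_assay"))
  if (!is_endpoint(plate))
    input_error("extract_controls needs an endpoint plate (one reading per well)")
  d <- plate$data  # already row-major ordered by the constructor
  pos <- d$value[d$role == "positive"]
  neg <- d$value[d$role == "negative"]
  if (!length(pos))
    input_error(sprintf("plate '%s' has no positive-control wells",
                        plate$assay_id))
  if (!length(neg))
    input_error(sprintf("plate '%s' has no negative-control wells",
                        plate$assay_id))
  control_groups(pos, neg)
}

#' Histogram of positive and negative control readouts
#'
#' Side-by-side histograms of the two control groups, the standard
#' first look at an assay evaluation plate.
#'
#' @param x A `control_groups` object.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further graphical parameters.
#' @export
plot.control_groups <- function(x, breaks = "Sturges", ...) {
  rng <- range(c(x$pos, x$neg))
  hp <- graphics::hist(x$pos, breaks = breaks, plot = FALSE)
  hn <- graphics::hist(x$neg, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(hp$counts, hn$counts))
  graphics::plot(hn, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlim = rng, ylim = ylim, main = "control distributions",
                 xlab = "readout", ...)
  graphics::plot(hp, col = grDevices::adjustcolor("firebrick", 0.6),
                 add = TRUE)
  graphics::legend("top", fill = c("firebrick", "steelblue"),
                   legend = c("positive", "negative"), bty = "n")
  invisible(x)
}
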