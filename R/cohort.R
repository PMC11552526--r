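#' Scan blocks: one transillumination measurement matrix
#'
#' A scan block holds the channels-by-time intensity matrix of one
#' (subject, breast side, wavelength) measurement of a continuous-wave
#' diffuse optical transillumination scan. Rows are measurement channels
#' (source-detector pairs, source-major order), columns are time frames.
#' Values are detector voltages in arbitrary units; normalized blocks may
#' contain negative values.
#'
#' @param values numeric matrix, channels x time frames. The number of rows
#'   must equal `n_sources * n_detectors`.
#' @param n_sources,n_detectors number of optical sources and detectors whose
#'   pairs form the channel axis (defaults 32 and 64).
#' @param wavelength_nm illumination wavelength, 760 or 830.
#' @param side breast side, `"left"` or `"right"`.
#' @return An object of class `scan_block`.
#' @seealso [channel_index()], [truncate_rest_phase()], [subset_channels()]
#' @export
#' @examples
#' b <- scan_block(matrix(rnorm(8), 4, 2), n_sources = 2, n_detectors = 2)
#' dim(b$values)
scan_block <- function(values, n_sources = 32L, n_detectors = 64L,
                       wavelength_nm = 760, side = "left") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (!all(is.finite(values)))
    stop_validation("scan block values must all be finite")
  n_sources <- as.integer(n_sources)
  n_detectors <- as.integer(n_detectors)
  if (n_sources < 1L || n_detectors < 1L)
    stop_validation("n_sources and n_detectors must be positive")
  if (nrow(values) != n_sources * n_detectors)
    stop_validation(sprintf(
      "row count %d does not equal n_sources x n_detectors = %d",
      nrow(values), n_sources * n_detectors))
  if (ncol(values) < 1L)
    stop_validation("a scan block needs at least one time frame")
  if (!wavelength_nm %in% c(760, 830))
    stop_validation("wavelength_nm must be 760 or 830")
  side <- match.arg(side, c("left", "right"))
  structure(
    list(values = unname(values), n_sources = n_sources,
         n_detectors = n_detectors, wavelength_nm = wavelength_nm,
         side = side),
    class = "scan_block")
}

#' Coerce a plain matrix to a scan block
#'
#' Convenience coercion for small examples and tests: each row becomes its own
#' source with a single detector.
#'
#' @param x numeric matrix or `scan_block`.
#' @param ... passed on to [scan_block()].
#' @return A `scan_block`.
#' @export
as_scan_block <- function(x, ...) {
  if (inherits(x, "scan_block")) return(x)
  scan_block(x, n_sources = nrow(x), n_detectors = 1L, ...)
}

#' @export
print.scan_block <- function(x, ...) {
  cat(sprintf("<scan_block> %s, %d nm: %d channels (%d sources x %d detectors) x %d frames\n",
              x$side, x$wavelength_nm, nrow(x$values), x$n_sources,
              x$n_detectors, ncol(x$values)))
  invisible(x)
}

#' @export
dim.scan_block <- function(x) dim(x$values)

block_key <- function(side, wavelength_nm) paste0(side, "_", wavelength_nm)

#' Subject records and cohorts
#'
#' A subject record bundles the four scan blocks of one subject (left/right
#' breast at 760 and 830 nm) with the cancer label and tumor laterality. A
#' cohort is an ordered list of subject records sharing block dimensions,
#' plus the instrument frame rate.
#'
#' @param subject_id character scalar, unique within a cohort.
#' @param blocks named list of exactly four `scan_block`s, keyed
#'   `left_760`, `left_830`, `right_760`, `right_830`.
#' @param cancer_positive logical scalar.
#' @param tumor_side `"left"`, `"right"`, or `"none"`. Must be `"none"` if and
#'   only if `cancer_positive` is `FALSE` (bilateral symmetric cancer is not
#'   modeled).
#' @return `subject_record()` returns a `subject_record`; `cohort()` a
#'   `cohort`.
#' @export
subject_record <- function(subject_id, blocks, cancer_positive, tumor_side) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    stop_validation("subject_id must be a single string")
  needed <- c("left_760", "left_830", "right_760", "right_830")
  if (!setequal(names(blocks), needed) || length(blocks) != 4L)
    stop_format(paste0("blocks must contain exactly the keys: ",
                       paste(needed, collapse = ", "),
                       "; missing: ",
                       paste(setdiff(needed, names(blocks)), collapse = ", ")))
  blocks <- blocks[needed]
  for (k in needed) {
    if (!inherits(blocks[[k]], "scan_block"))
      stop_format(sprintf("block '%s' is not a scan_block", k))
  }
  dims <- vapply(blocks, function(b) dim(b$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_format(sprintf("all four blocks of subject '%s' must share dimensions",
                        subject_id))
  tumor_side <- match.arg(tumor_side, c("left", "right", "none"))
  if (!is.logical(cancer_positive) || length(cancer_positive) != 1L)
    stop_validation("cancer_positive must be a single logical")
  if (cancer_positive != (tumor_side != "none"))
    stop_validation(sprintf(
      "subject '%s': cancer_positive must be TRUE exactly when tumor_side is not 'none'",
      subject_id))
  structure(
    list(subject_id = subject_id, blocks = blocks,
         cancer_positive = cancer_positive, tumor_side = tumor_side),
    class = "subject_record")
}

#' @param records list of `subject_record`s (unique subject ids, shared
#'   dimensions).
#' @param frame_rate_hz acquisition frame rate in Hz (default 1.8).
#' @rdname subject_record
#' @export
cohort <- function(records, frame_rate_hz = 1.8) {
  if (length(records) < 1L) stop_validation("a cohort needs at least one record")
  for (r in records)
    if (!inherits(r, "subject_record"))
      stop_validation("all cohort records must be subject_records")
  ids <- vapply(records, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids))
    stop_validation(sprintf("duplicated subject ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  d1 <- dim(records[[1]]$blocks[[1]]$values)
  for (r in records) {
    if (!identical(dim(r$blocks[[1]]$values), d1))
      stop_validation("all records in a cohort must share block dimensions")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop_validation("frame_rate_hz must be a positive number")
  structure(list(records = records, frame_rate_hz = frame_rate_hz),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$records)
  npos <- sum(vapply(x$records, function(r) r$cancer_positive, logical(1)))
  d <- dim(x$records[[1]]$blocks[[1]]$values)
  cat(sprintf("<cohort> %d subjects (%d cancer-positive), blocks %d channels x %d frames @ %.3g Hz\n",
              n, npos, d[1], d[2], x$frame_rate_hz))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$records)

#' Map a (source, detector) pair to its channel index
#'
#' Fixes the source-major convention identifying channel `r` with the pair
#' `(source, detector)`: `r = source * n_detectors + detector`. All indices
#' are 0-based; the full channel axis is the half-open range
#' `[0, n_sources * n_detectors)`.
#'
#' @param source 0-based source index (vectorized).
#' @param detector 0-based detector index (vectorized).
#' @param n_detectors number of detectors per source.
#' @param n_sources optional; when given, `source` is range-checked against it.
#' @return Integer channel index (0-based).
#' @export
#' @examples
#' channel_index(0, 0, 64)    # 0
#' channel_index(31, 63, 64)  # 2047
channel_index <- function(source, detector, n_detectors, n_sources = NULL) {
  if (any(detector < 0) || any(detector >= n_detectors))
    stop_range(sprintf("detector index out of range [0, %d)", n_detectors))
  if (any(source < 0))
    stop_range("source index out of range: negative")
  if (!is.null(n_sources) && any(source >= n_sources))
    stop_range(sprintf("source index out of range [0, %d)", n_sources))
  as.integer(source) * as.integer(n_detectors) + as.integer(detector)
}

#' Truncate a scan block to its leading rest-phase frames
#'
#' Imaging sessions begin with a resting period; recordings longer than the
#' common rest-phase length are truncated to the leading frames so that all
#' feature vectors have equal length.
#'
#' @param block a `scan_block`.
#' @param n_frames number of leading frames to keep (default 400).
#' @return A `scan_block` with `n_frames` time columns.
#' @export
truncate_rest_phase <- function(block, n_frames = 400L) {
  stopifnot(inherits(block, "scan_block"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop_validation("n_frames must be >= 1")
  T <- ncol(block$values)
  if (T < n_frames)
    stop_insufficient(
      sprintf("block has %d frames, %d required", T, n_frames),
      n_available = T, n_required = n_frames)
  block$values <- block$values[, seq_len(n_frames), drop = FALSE]
  block
}

#' Optode grid geometries
#'
#' A grid geometry names an ordered subset of sources and detectors, used to
#' emulate sparser instruments by discarding the channels of removed optodes.
#'
#' @param kept_sources,kept_detectors strictly increasing 0-based index
#'   vectors.
#' @param name label for reports (e.g. `"16x16/a"`).
#' @return An object of class `grid_geometry`.
#' @seealso [subset_channels()], [example_grids()]
#' @export
grid_geometry <- function(kept_sources, kept_detectors, name = NULL) {
  kept_sources <- as.integer(kept_sources)
  kept_detectors <- as.integer(kept_detectors)
  if (length(kept_sources) == 0L || length(kept_detectors) == 0L)
    stop_validation("grid geometry must keep at least one source and one detector")
  if (any(diff(kept_sources) <= 0) || any(kept_sources < 0))
    stop_validation("kept_sources must be strictly increasing and non-negative")
  if (any(diff(kept_detectors) <= 0) || any(kept_detectors < 0))
    stop_validation("kept_detectors must be strictly increasing and non-negative")
  if (is.null(name))
    name <- sprintf("%dx%d", length(kept_sources), length(kept_detectors))
  structure(list(kept_sources = kept_sources, kept_detectors = kept_detectors,
                 name = name),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> '%s': %d sources x %d detectors\n",
              x$name, length(x$kept_sources), length(x$kept_detectors)))
  invisible(x)
}

#' Restrict a scan block to an optode sub-grid
#'
#' Keeps exactly the channels formed by the retained sources and detectors,
#' ordered source-major by the kept lists, emulating an instrument with fewer
#' optodes.
#'
#' @param block a `scan_block`.
#' @param grid a [grid_geometry()] valid for the block's source and detector
#'   counts.
#' @return A `scan_block` with `length(kept_sources) * length(kept_detectors)`
#'   channels.
#' @export
subset_channels <- function(block, grid) {
  stopifnot(inherits(block, "scan_block"), inherits(grid, "grid_geometry"))
  if (max(grid$kept_sources) >= block$n_sources)
    stop_range(sprintf("source index %d out of range [0, %d)",
                       max(grid$kept_sources), block$n_sources))
  if (max(grid$kept_detectors) >= block$n_detectors)
    stop_range(sprintf("detector index %d out of range [0, %d)",
                       max(grid$kept_detectors), block$n_detectors))
  idx <- channel_index(rep(grid$kept_sources, each = length(grid$kept_detectors)),
                       rep(grid$kept_detectors, times = length(grid$kept_sources)),
                       block$n_detectors)
  scan_block(block$values[idx + 1L, , drop = FALSE],
             n_sources = length(grid$kept_sources),
             n_detectors = length(grid$kept_detectors),
             wavelength_nm = block$wavelength_nm, side = block$side)
}

# Apply a function to every block of every record, preserving structure.
map_blocks <- function(cohort_, f, ...) {
  cohort_$records <- lapply(cohort_$records, function(rec) {
    rec$blocks <- lapply(rec$blocks, f, ...)
    rec
  })
  cohort_
}

#' Restrict every block of a cohort to an optode sub-grid
#'
#' @param cohort_ a `cohort`.
#' @param grid a [grid_geometry()].
#' @return A `cohort` with subsetted blocks.
#' @export
subset_cohort <- function(cohort_, grid) {
  stopifnot(inherits(cohort_, "cohort"))
  map_blocks(cohort_, subset_channels, grid = grid)
}
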