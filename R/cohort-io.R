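#' Save and load cohort containers
#'
#' The on-disk cohort container is a directory holding `manifest.json`
#' (schema version, grid dimensions, frame count, frame rate, and the ordered
#' subject list with labels and laterality) plus one CSV matrix per
#' (subject, side, wavelength) named `<subject_id>_<side>_<wavelength>.csv`,
#' row = channel (source-major), column = time frame, no header. The
#' round-trip is lossless for values, labels, laterality and record order.
#'
#' Externally deposited data (e.g. public repositories of bilateral optical
#' mammography scans) can be used with the package by converting each
#' subject's four measurement matrices into this container; see
#' [cohort_from_matrices()] for an in-memory adapter.
#'
#' @param cohort_ a [cohort()].
#' @param path directory to create/read.
#' @return `load_cohort()` returns a `cohort`; `save_cohort()` returns `path`
#'   invisibly.
#' @export
save_cohort <- function(cohort_, path) {
  stopifnot(inherits(cohort_, "cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  b1 <- cohort_$records[[1]]$blocks[[1]]
  manifest <- list(
    schema_version = 1L,
    generator = paste0("bilatdot ", as.character(utils::packageVersion("bilatdot"))),
    n_sources = b1$n_sources,
    n_detectors = b1$n_detectors,
    n_frames = ncol(b1$values),
    frame_rate_hz = cohort_$frame_rate_hz,
    subjects = lapply(cohort_$records, function(r)
      list(subject_id = r$subject_id, cancer_positive = r$cancer_positive,
           tumor_side = r$tumor_side))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (r in cohort_$records) {
    for (key in names(r$blocks)) {
      f <- file.path(path, paste0(r$subject_id, "_", key, ".csv"))
      # %.17g guarantees a bit-exact double round-trip (fwrite's default 15
      # significant digits does not)
      m <- r$blocks[[key]]$values
      writeLines(apply(m, 1, function(row)
        paste(sprintf("%.17g", row), collapse = ",")), f)
    }
  }
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop_format(sprintf("missing manifest.json in '%s'", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  for (fld in c("n_sources", "n_detectors", "n_frames", "frame_rate_hz", "subjects"))
    if (is.null(manifest[[fld]]))
      stop_format(sprintf("manifest.json: missing field '%s'", fld))
  ns <- as.integer(manifest$n_sources)
  nd <- as.integer(manifest$n_detectors)
  nt <- as.integer(manifest$n_frames)
  records <- lapply(manifest$subjects, function(s) {
    if (is.null(s$subject_id) || is.null(s$cancer_positive) || is.null(s$tumor_side))
      stop_format("manifest.json: subject entry missing subject_id/cancer_positive/tumor_side")
    blocks <- list()
    for (side in c("left", "right")) {
      for (wl in c(760, 830)) {
        key <- block_key(side, wl)
        f <- file.path(path, paste0(s$subject_id, "_", key, ".csv"))
        if (!file.exists(f))
          stop_format(sprintf("missing matrix file for subject '%s', key '%s' (%s)",
                              s$subject_id, key, basename(f)))
        m <- as.matrix(data.table::fread(f, header = FALSE))
        dimnames(m) <- NULL
        if (nrow(m) != ns * nd || ncol(m) != nt)
          stop_format(sprintf(
            "%s: matrix is %dx%d but manifest declares %dx%d",
            basename(f), nrow(m), ncol(m), ns * nd, nt))
        blocks[[key]] <- scan_block(m, n_sources = ns, n_detectors = nd,
                                    wavelength_nm = wl, side = side)
      }
    }
    subject_record(s$subject_id, blocks,
                   isTRUE(s$cancer_positive), s$tumor_side)
  })
  cohort(records, frame_rate_hz = as.numeric(manifest$frame_rate_hz))
}

#' Build a cohort from in-memory matrices
#'
#' Adapter for data held outside the package's container format: supply one
#' channels-by-time matrix per (subject, side, wavelength) and the labels, and
#' get back a [cohort()] that every pipeline stage accepts. This is the
#' conversion point for externally deposited measurement archives whose native
#' layout the caller has already parsed.
#'
#' @param matrices nested list: `matrices[[i]]` is a named list with entries
#'   `left_760`, `left_830`, `right_760`, `right_830`, each a numeric matrix.
#' @param subject_ids character vector of subject identifiers.
#' @param tumor_sides `"left"`, `"right"` or `"none"` per subject; `"none"`
#'   means cancer-negative.
#' @param n_sources,n_detectors grid dimensions shared by all matrices.
#' @param frame_rate_hz acquisition frame rate in Hz.
#' @return A `cohort`.
#' @export
cohort_from_matrices <- function(matrices, subject_ids, tumor_sides,
                                 n_sources = 32L, n_detectors = 64L,
                                 frame_rate_hz = 1.8) {
  stopifnot(length(matrices) == length(subject_ids),
            length(matrices) == length(tumor_sides))
  records <- lapply(seq_along(matrices), function(i) {
    blocks <- list()
    for (side in c("left", "right")) {
      for (wl in c(760, 830)) {
        key <- block_key(side, wl)
        blocks[[key]] <- scan_block(matrices[[i]][[key]],
                                    n_sources = n_sources,
                                    n_detectors = n_detectors,
                                    wavelength_nm = wl, side = side)
      }
    }
    subject_record(subject_ids[i], blocks,
                   cancer_positive = tumor_sides[i] != "none",
                   tumor_side = tumor_sides[i])
  })
  cohort(records, frame_rate_hz = frame_rate_hz)
}
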