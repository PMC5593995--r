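# atomic write: temp file in the destination directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move temporary file onto %s", path))
  invisible(path)
}

#' Read a raw MIPS recording from CSV
#'
#' Expects a header and two columns, `time_s` and `phase_deg`.
#'
#' @param path input file.
#' @param schedule an [injection_schedule()] attached to the series (needed
#'   later by [block_smooth()]).
#' @return a `raw_mips` data frame.
#' @export
read_raw_series <- function(path, schedule = injection_schedule()) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "phase_deg") %in% names(df)))
    stop(sprintf("%s: expected columns time_s, phase_deg", path))
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$phase_deg)))
    stop(sprintf("%s: non-finite values in series", path))
  if (any(diff(df$time_s) <= 0))
    stop(sprintf("%s: time_s must be strictly increasing", path))
  class(df) <- c("raw_mips", "data.frame")
  attr(df, "schedule") <- schedule
  df
}

#' Write a raw MIPS recording to CSV
#'
#' @param raw a `raw_mips` data frame.
#' @param path output file (written atomically).
#' @export
write_raw_series <- function(raw, path) {
  stopifnot(is.data.frame(raw), all(c("time_s", "phase_deg") %in% names(raw)))
  write_atomic(function(tmp)
    utils::write.csv(raw[c("time_s", "phase_deg")], tmp, row.names = FALSE),
    path)
}

#' Read a block series from TSV
#'
#' Expects columns `time_min`, `blood_ml`, `value`.
#'
#' @param path input file.
#' @return a [block_series()].
#' @export
read_block_series <- function(path) {
  df <- utils::read.delim(path)
  need <- c("time_min", "blood_ml", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  block_series(df$time_min, df$blood_ml, df$value)
}

#' Write a block series to TSV
#'
#' Values are written with full double precision so a write/read round trip
#' is exact to within 1e-12.
#'
#' @param series a [block_series()].
#' @param path output file (written atomically).
#' @export
write_block_series <- function(series, path) {
  stopifnot(inherits(series, "block_series"))
  write_atomic(function(tmp) {
    df <- series
    df[] <- lapply(df, function(col) sprintf("%.15g", col))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Read an MR volume from NIfTI-1
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return an [mr_volume()] with spacing from the header pixdim.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  mr_volume(array(as.numeric(img), dim(img)[1:3]), spacing)
}

#' Write an MR volume (or mask) to NIfTI-1
#'
#' Masks (logical or 0/1 integer arrays with a `spacing` attribute) are
#' written as unsigned 8-bit, intensity volumes as float.
#'
#' @param vol an [mr_volume()], or a logical/integer array with a `spacing`
#'   attribute.
#' @param path output file.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "mr_volume")) {
    data <- vol$data
    spacing <- vol$spacing
    dt <- "float"
  } else {
    stopifnot(is.array(vol))
    spacing <- attr(vol, "spacing")
    if (is.null(spacing)) stop("array volumes need a spacing attribute")
    data <- array(as.integer(vol), dim(vol))
    dt <- "uint8"
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Write a report as JSON
#'
#' @param report a `correlation_report`, or any list of plain values.
#' @param path output file (written atomically).
#' @export
write_report <- function(report, path) {
  x <- if (inherits(report, "correlation_report")) as.list(report) else report
  write_atomic(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null"),
    path)
}

# frozen checksums of the packaged cohort tables
fixture_md5 <- c(table1_mips.tsv = "976375bef484047c31eaf69df7bea910",
                 table2_csf.tsv = "aace9407e80f09e4686c529cf46cc8d7")

#' Load the packaged eight-rabbit cohort tables
#'
#' Table 1: block-smoothed, baseline-normalized MIPS (dimensionless, about
#' 100); Table 2: quantified CSF volume (ml); both 8 animals x 9 observation
#' times, keyed by injected blood volume. Values are stored at the published
#' decimal precision and are checksummed: a modified fixture file is a hard
#' error.
#'
#' @return list of class `fixture_bundle` with `table1` (MIPS), `table2`
#'   (CSF), both data frames with columns `time_min`, `blood_ml`,
#'   `rabbit_1..rabbit_8`.
#' @examples
#' fx <- load_fixture_tables()
#' fx$table1$rabbit_1[1]  # 100.2652
#' @export
load_fixture_tables <- function() {
  paths <- vapply(names(fixture_md5), function(f)
    system.file("extdata", f, package = "mipscsf", mustWork = TRUE),
    character(1))
  sums <- tools::md5sum(paths)
  bad <- sums != fixture_md5
  if (any(bad))
    stop("fixture checksum mismatch: ", paste(names(fixture_md5)[bad],
                                              collapse = ", "))
  tabs <- lapply(paths, utils::read.delim)
  structure(list(table1 = tabs[[1]], table2 = tabs[[2]]),
            class = "fixture_bundle")
}

#' Write cohort tables to TSV
#'
#' Writes the MIPS and CSF tables of a simulated cohort in the fixture
#' layout (`time_min`, `blood_ml`, `rabbit_1..N`, tab-separated).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return paths of the two files, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mips_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    out <- df
    out[] <- lapply(out, function(col)
      if (is.numeric(col)) sprintf("%.15g", col) else col)
    out
  }
  p1 <- file.path(dir, "mips_table.tsv")
  p2 <- file.path(dir, "csf_table.tsv")
  write_atomic(function(tmp) utils::write.table(fmt(cohort$mips_table), tmp,
    sep = "\t", quote = FALSE, row.names = FALSE), p1)
  write_atomic(function(tmp) utils::write.table(fmt(cohort$csf_table), tmp,
    sep = "\t", quote = FALSE, row.names = FALSE), p2)
  invisible(c(p1, p2))
}
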