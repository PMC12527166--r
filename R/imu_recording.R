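# imu_io: data model and file I/O for inertial recordings.
#
# Axis convention (fixed package-wide): x = naso-occipital (fore-aft),
# y = interaural (medio-lateral), z = head-vertical.  Acceleration in g,
# angular velocity in deg/s.  Time is implicit (sample index / rate).

#' Construct an IMU recording
#'
#' Bundles synchronized accelerometer and gyroscope streams with their
#' sampling rate and free-form metadata.
#'
#' @param accel n x 3 numeric matrix of acceleration in g (columns x, y, z:
#'   fore-aft, interaural, head-vertical).
#' @param gyro n x 3 numeric matrix of angular velocity in deg/s about the
#'   same axes.
#' @param rate_hz sampling rate in Hz (> 0).
#' @param meta named list of free-form metadata (animal id, session, group).
#' @return an object of class `imu_recording`.
#' @examples
#' rec <- imu_recording(matrix(c(0, 0, 1), 10, 3, byrow = TRUE),
#'                      matrix(0, 10, 3), rate_hz = 300)
#' rec
#' @export
imu_recording <- function(accel, gyro, rate_hz, meta = list()) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  storage.mode(accel) <- "double"; storage.mode(gyro) <- "double"
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop_schema("accel and gyro must each have 3 columns (x, y, z)")
  if (nrow(accel) != nrow(gyro))
    stop_schema("accel and gyro lengths differ (%d vs %d)", nrow(accel), nrow(gyro))
  if (nrow(accel) < 1L) stop_schema("recording must contain at least one sample")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) || rate_hz <= 0)
    stop_config("rate_hz must be a single positive number")
  bad <- which(!stats::complete.cases(cbind(accel, gyro)) |
                 !is.finite(rowSums(accel) + rowSums(gyro)))
  if (length(bad))
    stop_value("non-finite samples at rows: %s",
               paste(utils::head(bad, 10L), collapse = ", "))
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(list(accel = accel, gyro = gyro, rate_hz = as.numeric(rate_hz),
                 meta = meta),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- nrow(x$accel)
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.2f s)\n",
              n, x$rate_hz, n / x$rate_hz))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples and duration of a recording
#' @param rec an [imu_recording()].
#' @return number of samples.
#' @export
n_samples <- function(rec) nrow(rec$accel)

#' @rdname n_samples
#' @return duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$accel) / rec$rate_hz

#' Read an IMU recording from CSV
#'
#' The CSV dialect is: comma-separated values with a header row
#' `ax,ay,az,gx,gy,gz`, preceded by optional comment lines of the form
#' `# rate_hz=<float>` and `# meta:<key>=<value>`.  An optional leading
#' `time` column is accepted and used only to verify that the sampling rate
#' is constant (1% tolerance).
#'
#' @param path file path.
#' @param rate_hz sampling rate in Hz; required unless embedded in the file
#'   header.
#' @param units length-2 character, units of the acceleration and gyroscope
#'   columns: `c("g", "degps")` (default). `"mps2"` (m/s^2) and `"radps"`
#'   are converted on load.
#' @param na_action `"error"` (default) rejects files containing
#'   non-finite samples, reporting the row indices; `"impute"` fills them by
#'   linear interpolation.
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, rate_hz = NULL, units = c("g", "degps"),
                           na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop_config("file not found: %s", path)
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop_schema("empty file: %s", path)
    if (startsWith(line, "#")) hdr <- c(hdr, line) else break
  }
  meta <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (grepl("^rate_hz=", h)) {
      rate_hz <- rate_hz %||% as.numeric(sub("^rate_hz=", "", h))
    } else if (grepl("^meta:", h)) {
      kv <- sub("^meta:", "", h)
      key <- sub("=.*$", "", kv)
      meta[[key]] <- sub("^[^=]*=", "", kv)
    }
  }
  cols <- strsplit(line, ",")[[1]]
  df <- read.csv(textConnection(c(line, readLines(con))), header = TRUE,
                 comment.char = "")
  required <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols))
    stop_schema("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.null(rate_hz)) {
    if (!"time" %in% cols)
      stop_config("sampling rate absent: supply rate_hz or a '# rate_hz=' header")
    dt <- diff(df$time)
    if (length(dt) < 1L || any(dt <= 0))
      stop_config("time column is not strictly increasing")
    rate_hz <- 1 / median(dt)
  }
  if ("time" %in% cols && nrow(df) > 2L) {
    dt <- diff(df$time)
    if (any(dt <= 0) || (max(dt) - min(dt)) / median(dt) > 0.01)
      stop_config("time column implies a non-constant sampling rate (>1%% jitter)")
  }
  accel <- as.matrix(df[required[1:3]])
  gyro <- as.matrix(df[required[4:6]])
  bad <- which(!is.finite(rowSums(accel) + rowSums(gyro)))
  if (length(bad)) {
    if (na_action == "error")
      stop_value("non-finite samples at rows: %s",
                 paste(utils::head(bad, 10L), collapse = ", "))
    for (j in 1:3) {
      accel[, j] <- approx_fill(accel[, j])
      gyro[, j] <- approx_fill(gyro[, j])
    }
  }
  if (units[1] == "mps2") accel <- accel / 9.80665
  else if (units[1] != "g") stop_config("unknown acceleration unit: %s", units[1])
  if (units[2] == "radps") gyro <- gyro * 180 / pi
  else if (units[2] != "degps") stop_config("unknown gyroscope unit: %s", units[2])
  imu_recording(accel, gyro, rate_hz, meta)
}

approx_fill <- function(v) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  if (all(bad)) stop_value("a channel contains no finite samples to impute from")
  if (sum(!bad) == 1L) return(rep(v[!bad], length(v)))
  idx <- seq_along(v)
  stats::approx(idx[!bad], v[!bad], xout = idx, rule = 2)$y
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_recording()]: emits the `# rate_hz=` header, one
#' `# meta:` line per metadata entry, and the six signal columns at full
#' double precision (round-trips to >= 15 significant digits).
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  hdr <- sprintf("# rate_hz=%.17g", rec$rate_hz)
  if (length(rec$meta))
    hdr <- c(hdr, sprintf("# meta:%s=%s", names(rec$meta),
                          vapply(rec$meta, as.character, character(1))))
  m <- cbind(rec$accel, rec$gyro)
  cols <- lapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]))
  body <- do.call(paste, c(cols, list(sep = ",")))
  lines <- c(hdr, "ax,ay,az,gx,gy,gz", body)
  ok <- try(writeLines(lines, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop_config("cannot write to %s", path)
  invisible(path)
}
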