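# Session container: a directory holding float64 binary arrays plus a
# schema-validated JSON sidecar (sampling rates, geometry, schedule,
# seeds, append-only provenance) and the trial table as CSV.

SCHEMA_VERSION <- 1L

write_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8, endian = "little")
}

read_array <- function(path, dims) {
  n_expected <- prod(dims)
  sz <- file.info(path)$size
  if (is.na(sz) || sz != 8 * n_expected)
    stop(sprintf("array file '%s' has %s bytes; expected %d (shape %s)",
                 basename(path), ifelse(is.na(sz), "no", sz), 8 * n_expected,
                 paste(dims, collapse = "x")))
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "double", n_expected, size = 8, endian = "little"), dims)
}

#' Write a session to a container directory
#'
#' @param session List with `recording` and `trials` (as returned by
#'   [simulate_session()] or [read_session()]).
#' @param path Directory to create/write.
#' @param provenance Optional character step appended to the processing
#'   history.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, provenance = NULL) {
  rec <- session$recording
  if (!inherits(rec, "lam_recording")) stop("`session$recording` must be a lam_recording")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrays <- list()
  for (nm in c("lfp", "mua", "wideband")) {
    if (!is.null(rec[[nm]])) {
      write_array(rec[[nm]], file.path(path, paste0(nm, ".bin")))
      arrays[[nm]] <- dim(rec[[nm]])
    }
  }
  if (!is.null(rec$eye)) {
    write_array(rec$eye$x, file.path(path, "eye_x.bin"))
    write_array(rec$eye$y, file.path(path, "eye_y.bin"))
    arrays$eye_x <- dim(rec$eye$x)
    arrays$eye_y <- dim(rec$eye$y)
  }
  prev <- character(0)
  sidecar_path <- file.path(path, "sidecar.json")
  if (file.exists(sidecar_path)) {
    old <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    prev <- old$provenance
  }
  sidecar <- list(
    schema_version = SCHEMA_VERSION,
    penetration_id = rec$penetration_id,
    task = rec$task,
    schedule = rec$schedule,
    fs_lfp = rec$fs_lfp, fs_mua = rec$fs_mua,
    fs_eye = if (!is.null(rec$eye)) rec$eye$fs else NULL,
    t_start = if (!is.null(rec$time_lfp)) rec$time_lfp[1] else rec$time_mua[1],
    channel_depths = rec$channel_depths,
    seed = rec$seed,
    arrays = arrays,
    provenance = c(prev, provenance %||% "write_session"))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  write.csv(session$trials, file.path(path, "trials.csv"), row.names = FALSE)
  invisible(path)
}

validate_sidecar <- function(sc) {
  req <- c("schema_version", "task", "fs_lfp", "fs_mua", "channel_depths",
           "arrays", "t_start")
  miss <- setdiff(req, names(sc))
  if (length(miss))
    stop("sidecar is missing field(s): ", paste(miss, collapse = ", "))
  if (sc$schema_version != SCHEMA_VERSION)
    stop("unknown sidecar schema version: ", sc$schema_version)
  for (f in c("fs_lfp", "fs_mua")) {
    if (!is.numeric(sc[[f]]) || sc[[f]] <= 0)
      stop("sidecar field `", f, "` must be a positive number")
  }
  d <- diff(sc$channel_depths)
  if (any(d <= 0)) stop("sidecar field `channel_depths` must be strictly increasing")
  invisible(sc)
}

#' Read a session from a container directory
#'
#' Validates the JSON sidecar (schema version, positive sampling rates,
#' monotone channel depths, array shapes vs file sizes) and reconstructs
#' the in-memory session.
#'
#' @param path Container directory written by [write_session()].
#' @return List with `recording` (class `lam_recording`) and `trials`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no such session directory: ", path)
  sidecar_path <- file.path(path, "sidecar.json")
  if (!file.exists(sidecar_path)) stop("missing sidecar.json in ", path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  validate_sidecar(sc)
  rec <- list(fs_lfp = sc$fs_lfp, fs_mua = sc$fs_mua,
              channel_depths = sc$channel_depths,
              penetration_id = sc$penetration_id,
              task = sc$task, schedule = as.list(sc$schedule),
              seed = sc$seed, provenance = sc$provenance)
  for (nm in c("lfp", "mua", "wideband")) {
    if (!is.null(sc$arrays[[nm]])) {
      f <- file.path(path, paste0(nm, ".bin"))
      if (!file.exists(f)) stop("missing array file: ", basename(f))
      rec[[nm]] <- read_array(f, sc$arrays[[nm]])
    }
  }
  if (!is.null(rec$lfp))
    rec$time_lfp <- sc$t_start + (seq_len(dim(rec$lfp)[3]) - 1L) * 1000 / sc$fs_lfp
  if (!is.null(rec$mua))
    rec$time_mua <- sc$t_start + (seq_len(dim(rec$mua)[3]) - 1L) * 1000 / sc$fs_mua
  if (!is.null(sc$arrays$eye_x)) {
    rec$eye <- list(x = read_array(file.path(path, "eye_x.bin"), sc$arrays$eye_x),
                    y = read_array(file.path(path, "eye_y.bin"), sc$arrays$eye_y),
                    fs = sc$fs_eye,
                    time = sc$t_start +
                      (seq_len(sc$arrays$eye_x[2]) - 1L) * 1000 / sc$fs_eye)
  }
  class(rec) <- "lam_recording"
  trials_path <- file.path(path, "trials.csv")
  if (!file.exists(trials_path)) stop("missing trials.csv in ", path)
  trials <- read.csv(trials_path, stringsAsFactors = FALSE)
  list(recording = rec, trials = trials)
}
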