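# Portable session container: a directory holding JSON metadata, the epoch
# array as IEEE-754 little-endian doubles, and CSV tables for trials and
# layout.  Round trips are bit-identical.

CONTAINER_VERSION <- "1.0"

#' Write an epoched session to a directory container
#'
#' Layout: `meta.json` (version, fs, time axis, dimensions, artifacts,
#' provenance), `data.bin` (trials x channels x samples doubles,
#' column-major, little-endian), `trials.csv`, `layout.csv`.
#'
#' @param epochs `epoched_data`.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_session <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoched_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(version = CONTAINER_VERSION,
               fs = epochs$fs,
               time_ms = epochs$time_ms,
               dims = dim(epochs$data),
               artifacts = epochs$artifacts,
               provenance = epochs$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  close(con)
  utils::write.csv(as.data.frame(epochs$trials), file.path(path, "trials.csv"),
                   row.names = FALSE)
  lay <- data.frame(channel_id = epochs$layout$channel_ids,
                    x = epochs$layout$positions_3d[, 1],
                    y = epochs$layout$positions_3d[, 2],
                    z = epochs$layout$positions_3d[, 3],
                    type = epochs$layout$channel_type)
  utils::write.csv(lay, file.path(path, "layout.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an epoched session from a directory container
#'
#' @param path directory written by [write_session()].
#' @return `epoched_data`.
#' @export
read_session <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop_("no session at '%s': meta.json absent", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$version)) stop_("corrupt session: version field absent")
  if (!identical(as.character(meta$version), CONTAINER_VERSION)) {
    stop_("unsupported container version '%s' (expected %s); re-export the session with this package version",
          meta$version, CONTAINER_VERSION)
  }
  if (!file.exists(file.path(path, "trials.csv"))) stop_("trials table absent")
  if (!file.exists(file.path(path, "layout.csv"))) stop_("layout table absent")
  if (!file.exists(file.path(path, "data.bin"))) stop_("data array absent")
  dims <- as.integer(meta$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  x <- readBin(con, "double", n = prod(dims), size = 8L, endian = "little")
  close(con)
  if (length(x) != prod(dims)) {
    stop_("data array has %d values but dims imply %d", length(x), prod(dims))
  }
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(trials) != dims[1]) {
    stop_("trials table has %d rows but data has %d trials", nrow(trials), dims[1])
  }
  class(trials) <- c("trial_table", "data.frame")
  lay <- utils::read.csv(file.path(path, "layout.csv"), stringsAsFactors = FALSE)
  layout <- sensor_layout(lay$channel_id, as.matrix(lay[, c("x", "y", "z")]),
                          lay$type)
  arts <- meta$artifacts
  if (length(arts) == 0) arts <- list()
  prov <- meta$provenance
  if (length(prov) == 0) prov <- list()
  epoched_data(array(x, dims), meta$fs, meta$time_ms, trials, layout,
               artifacts = arts, provenance = prov)
}
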