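## Tab-separated interchange formats for event and ground-truth tables.

.event_cols <- c("particle_id", "fluorophore_index", "frame",
                 "x_nm", "y_nm", "counts_ch1", "counts_ch2")

#' Write / read a fluorophore event table
#'
#' Events are stored as tab-separated text with header columns
#' `particle_id`, `fluorophore_index`, `frame`, `x_nm`, `y_nm`,
#' `counts_ch1`, `counts_ch2`.
#'
#' @param events Event data.frame (see [emit_events()]).
#' @param path File path.
#' @return `read_events` returns the event data.frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(.event_cols %in% names(events)))
  utils::write.table(events[.event_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t")
  missing <- setdiff(.event_cols, names(ev))
  if (length(missing))
    stop("event table is missing columns: ", paste(missing, collapse = ", "))
  ev
}

#' Write the ground-truth table of a simulated population
#'
#' One row per particle: class label, side length, orientation angles and
#' the three dipole azimuths, tab-separated.
#'
#' @param particles List of `trimer_particle` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(particles, path) {
  tab <- do.call(rbind, lapply(particles, function(p) {
    data.frame(particle_id = p$particle_id, class = p$class_label,
               side_nm = p$side_length,
               yaw = p$orientation[1], pitch = p$orientation[2],
               roll = p$orientation[3],
               azimuth_1 = p$dipole_azimuths[1],
               azimuth_2 = p$dipole_azimuths[2],
               azimuth_3 = p$dipole_azimuths[3])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-channel TIFF stack
#'
#' Thin wrapper over the tiff package (only needed if you use this reader):
#' returns a list of numeric matrices, one per directory in the file.
#'
#' @param path TIFF file path.
#' @return List of matrices.
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF stacks requires the 'tiff' package")
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
}
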