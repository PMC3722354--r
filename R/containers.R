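#' Epoch-set container
#'
#' Trial-level sensor data: a trials x sensors x time array with a common
#' peristimulus time axis and one condition label per trial.
#'
#' @param data trials x sensors x time array.
#' @param times_ms peristimulus time axis, ms.
#' @param conditions character vector, one label per trial.
#' @param dt sample interval, s.
#' @param provenance free-text processing notes (e.g. cleaning status).
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, times_ms, conditions, dt = 1 / 480,
                          provenance = character(0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times_ms),
            dim(data)[1] == length(conditions))
  structure(list(data = data, times_ms = times_ms,
                 conditions = as.character(conditions), dt = dt,
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d sensors x %d samples (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms)))
  tab <- table(x$conditions)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Averaged (evoked) sensor data
#'
#' @param data sensors x time matrix.
#' @param times_ms time axis, ms.
#' @param condition condition label.
#' @param weights optional trials x time robust weights used in averaging.
#' @return An object of class `evoked`.
#' @export
new_evoked <- function(data, times_ms, condition = "average",
                       weights = NULL) {
  stopifnot(ncol(data) == length(times_ms))
  structure(list(data = data, times_ms = times_ms, condition = condition,
                 weights = weights),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %d sensors x %d samples, condition '%s'\n",
              nrow(x$data), ncol(x$data), x$condition))
  invisible(x)
}

new_gfp <- function(values, times_ms, condition = "average") {
  structure(list(values = values, times_ms = times_ms,
                 condition = condition),
            class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples (%g..%g ms), peak %.3g\n",
              length(x$values), min(x$times_ms), max(x$times_ms),
              max(x$values)))
  invisible(x)
}

#' Export a GFP series as CSV (time_ms, value)
#' @param gfp a `gfp_series`.
#' @param path output file.
#' @export
write_gfp_csv <- function(gfp, path) {
  utils::write.csv(data.frame(time_ms = gfp$times_ms, value = gfp$values),
                   path, row.names = FALSE)
  invisible(path)
}
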