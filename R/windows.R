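#' Time-window scheme
#'
#' Windows are contiguous, non-overlapping, time-ordered blocks of (strided)
#' frame indices. A trailing block shorter than `frames_per_window` is dropped
#' by default: a partial window changes the per-window frame count in the
#' windowed-RDF normalisation and would silently alter noise levels.
#'
#' @param frames_per_window frames per window (N_W), >= 1.
#' @param stride keep every `stride`-th frame before windowing (default 1).
#' @param partial `"drop"` (default) or `"keep"` for the trailing short block.
#' @return object of class `window_scheme`.
#' @export
window_scheme <- function(frames_per_window, stride = 1L,
                          partial = c("drop", "keep")) {
  frames_per_window <- as.integer(frames_per_window)
  stride <- as.integer(stride)
  partial <- match.arg(partial)
  if (frames_per_window < 1L) domain_error("frames_per_window must be >= 1")
  if (stride < 1L) domain_error("stride must be >= 1")
  structure(list(frames_per_window = frames_per_window, stride = stride,
                 partial = partial), class = "window_scheme")
}

#' Partition frames into windows
#'
#' @param n_frames total frame count of the trajectory.
#' @param scheme a [window_scheme].
#' @return list of integer vectors of 1-based frame indices, each with a
#'   `partial` attribute; empty (with a warning) if no complete window fits
#'   under the `"drop"` policy.
#' @export
partition_windows <- function(n_frames, scheme) {
  if (n_frames < 1L) domain_error("n_frames must be >= 1")
  used <- seq(1L, n_frames, by = scheme$stride)
  nw <- scheme$frames_per_window
  n_full <- length(used) %/% nw
  blocks <- list()
  for (w in seq_len(n_full))
    blocks[[w]] <- structure(used[((w - 1L) * nw + 1L):(w * nw)],
                             partial = FALSE)
  rest <- length(used) - n_full * nw
  if (rest > 0L) {
    if (scheme$partial == "keep") {
      blocks[[n_full + 1L]] <- structure(used[(n_full * nw + 1L):length(used)],
                                         partial = TRUE)
    } else if (n_full == 0L) {
      warning(sprintf(
        "frames_per_window (%d) exceeds available frames (%d); no windows",
        nw, length(used)))
    }
  }
  blocks
}

window_metadata <- function(blocks, time) {
  if (!length(blocks))
    return(data.frame(window = integer(0), start_frame = integer(0),
                      end_frame = integer(0), start_time_ps = numeric(0),
                      n_frames = integer(0), partial = logical(0)))
  data.frame(
    window = seq_along(blocks),
    start_frame = vapply(blocks, function(b) b[1], integer(1)),
    end_frame = vapply(blocks, function(b) b[length(b)], integer(1)),
    start_time_ps = vapply(blocks, function(b) time[b[1]], numeric(1)),
    n_frames = lengths(blocks),
    partial = vapply(blocks, function(b) isTRUE(attr(b, "partial")), logical(1)))
}
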