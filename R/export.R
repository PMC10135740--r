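# Tidy CSV and HDF5 array-container exports. CSV is long-format (one row per
# ref group x target group x window/lag x bin). The HDF5 layout mirrors the
# in-memory arrays: /g (or /G, /n), /counts, /bin_centers, plus
# /window_start_ps or /lags_ps, with scalar metadata as attributes of /meta.

result_long_df <- function(x) {
  grid <- x$grid
  if (inherits(x, "rdf_result")) {
    dn <- dimnames(x$g)
    expand_df <- expand.grid(ref_group = dn[[1]], target_group = dn[[2]],
                             bin = seq_len(grid$n_bins),
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    expand_df$bin_center_nm <- grid$centers[expand_df$bin]
    expand_df$g <- as.vector(x$g)
    expand_df$count <- as.vector(x$counts)
    expand_df$bin <- NULL
    expand_df
  } else if (inherits(x, "trrdf_result") ||
             inherits(x, "coordination_profile")) {
    arr <- if (!is.null(x$g)) x$g else x$n
    valname <- if (!is.null(x$g)) "g" else "n"
    dn <- dimnames(arr)
    nw <- dim(arr)[3]
    df <- expand.grid(ref_group = dn[[1]], target_group = dn[[2]],
                      window = seq_len(nw), bin = seq_len(grid$n_bins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$bin_center_nm <- grid$centers[df$bin]
    df$start_time_ps <- x$windows$start_time_ps[df$window]
    df[[valname]] <- as.vector(arr)
    if (!is.null(x$counts)) df$count <- as.vector(x$counts)
    df$bin <- NULL
    df
  } else if (inherits(x, "vhf_result")) {
    dn <- dimnames(x$G)
    df <- expand.grid(ref_group = dn[[1]], target_group = dn[[2]],
                      lag_index = seq_along(x$lags),
                      bin = seq_len(grid$n_bins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$lag_frames <- x$lags[df$lag_index]
    df$lag_ps <- x$lags_ps[df$lag_index]
    df$bin_center_nm <- grid$centers[df$bin]
    df$G <- as.vector(x$G)
    df$count <- as.vector(x$counts)
    df$lag_index <- NULL; df$bin <- NULL
    df
  } else domain_error("unsupported result type for export")
}

#' Write a result as long-format CSV
#'
#' @param x an `rdf_result`, `trrdf_result`, `coordination_profile` or
#'   `vhf_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(result_long_df(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a result as an HDF5 array container
#'
#' Layout: `/g` (RDF / windowed RDF), `/n` (coordination), or `/G` (van Hove)
#' with dimensions `[ref, target, (window|lag,) bin]`, `/counts`,
#' `/bin_centers`, and `/window_start_ps` or `/lags_ps` where applicable;
#' group names are stored under `/ref_groups` and `/target_groups`. Requires
#' the rhdf5 package.
#'
#' @inheritParams write_result_csv
#' @export
write_result_h5 <- function(x, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    format_error("HDF5 export requires the rhdf5 package; use write_result_csv()")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  main <- if (!is.null(x$g)) list(name = "g", arr = x$g)
          else if (!is.null(x$n)) list(name = "n", arr = x$n)
          else list(name = "G", arr = x$G)
  rhdf5::h5write(main$arr, path, main$name)
  if (!is.null(x$counts)) rhdf5::h5write(x$counts, path, "counts")
  rhdf5::h5write(x$grid$centers, path, "bin_centers")
  dn <- dimnames(main$arr)
  rhdf5::h5write(dn[[1]], path, "ref_groups")
  rhdf5::h5write(dn[[2]], path, "target_groups")
  if (!is.null(x$windows) && nrow(x$windows))
    rhdf5::h5write(x$windows$start_time_ps, path, "window_start_ps")
  if (!is.null(x$lags_ps)) rhdf5::h5write(x$lags_ps, path, "lags_ps")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read back an HDF5 array container written by [write_result_h5()]
#' @param path file path.
#' @return named list of the stored datasets.
#' @export
read_result_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    format_error("HDF5 import requires the rhdf5 package")
  names <- rhdf5::h5ls(path)$name
  out <- lapply(names, function(nm) rhdf5::h5read(path, nm))
  names(out) <- names
  rhdf5::h5closeAll()
  out
}

#' Export per-window coordination data for heat-map rendering
#'
#' Wide matrix `[window x bin]` of n(r, W) for one (ref, target) pair — the
#' data contract behind windowed coordination heat maps (time on one axis,
#' radius on the other); rendering is left to the caller.
#'
#' @param coord a windowed `coordination_profile`.
#' @param ref,target group name or index (default 1).
#' @return matrix with windows as rows (rownames = start time, ps) and bins
#'   as columns (colnames = bin centres, nm).
#' @export
coordination_heatmap_matrix <- function(coord, ref = 1L, target = 1L) {
  m <- coord$n[ref, target, , , drop = TRUE]
  m <- matrix(m, nrow = dim(coord$n)[3])
  rownames(m) <- format(coord$windows$start_time_ps)
  colnames(m) <- format(coord$grid$centers)
  m
}
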