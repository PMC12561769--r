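# Persistence helpers: grids to NIfTI / plain text, traces to CSV, run
# metadata to JSON.

#' Save a medium grid
#'
#' `write_medium_grid` writes the property volumes of a [medium_grid()] as
#' NIfTI files (`<prefix>_speed.nii.gz`, `<prefix>_density.nii.gz`, plus
#' labels/CT numbers when present); `read_medium_grid` restores the grid.
#'
#' @param medium a [medium_grid()].
#' @param prefix output path prefix.
#' @return `write_medium_grid` returns the written paths invisibly.
#' @export
write_medium_grid <- function(medium, prefix) {
  stopifnot(inherits(medium, "medium_grid"))
  paths <- character(0)
  for (field in c("speed", "density", "labels", "hu")) {
    val <- medium[[field]]
    if (is.null(val)) next
    p <- paste0(prefix, "_", field, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(val * 1.0,
                                       pixdim = rep(medium$spacing, 3)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_medium_grid
#' @param spacing voxel size in mm (read back from the NIfTI header when NULL).
#' @export
read_medium_grid <- function(prefix, spacing = NULL) {
  get_field <- function(field) {
    p <- paste0(prefix, "_", field, ".nii.gz")
    if (!file.exists(p)) return(NULL)
    img <- RNifti::readNifti(p)
    if (is.null(spacing)) spacing <<- RNifti::pixdim(img)[1]
    array(as.numeric(img), dim = dim(img))
  }
  speed <- get_field("speed")
  if (is.null(speed)) stop("no speed volume at ", prefix, call. = FALSE)
  medium_grid(speed, get_field("density"), spacing = spacing,
              labels = get_field("labels"), hu = get_field("hu"))
}

#' Write detector traces to CSV
#'
#' One column of times (s) plus one pressure column (Pa) per detector.
#'
#' @param traces the list returned by [propagate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(length(traces) >= 1L)
  t <- traces[[1]]$t0 + (seq_along(traces[[1]]$samples) - 1) * traces[[1]]$dt
  df <- data.frame(time_s = t)
  for (m in seq_along(traces))
    df[[sprintf("p_pa_det%d", m)]] <- traces[[m]]$samples
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata alongside an output
#'
#' Serialises the propagation metadata (scheme, CFL number, precision,
#' source mode, grid parameters) plus any extra fields to JSON.
#'
#' @param traces the list returned by [propagate()] (its `metadata`
#'   attribute is written), or a metadata list directly.
#' @param path output JSON path.
#' @param extra named list of additional fields (seeds, study labels, ...).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(traces, path, extra = list()) {
  meta <- attr(traces, "metadata") %||% traces
  meta$package_version <- as.character(utils::packageVersion("protorange"))
  jsonlite::write_json(c(meta, extra), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
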