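#' Read a 3D volume
#'
#' Reads a density volume from NIfTI (`.nii` / `.nii.gz`, via RNifti) or
#' from the package's plain-text raw container (`.uvol`, see
#' [write_volume()]). The flattened vector follows the x-fastest ordering
#' used everywhere in the package. 4D or higher-rank inputs are rejected.
#'
#' @param path Input file.
#' @param clamp_negative Clamp negative voxels to zero with a warning
#'   instead of leaving them as read.
#' @return List with `values` (flattened length-`n` vector), `dim`
#'   (`c(n1, n2, n3)`) and `spacing` (`c(dx, dy, dz)`).
#' @export
read_volume <- function(path, clamp_negative = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop(sprintf("expected a rank-3 volume; %s has rank %d", path, length(d)))
    pix <- RNifti::pixdim(img)
    out <- list(values = as.double(img), dim = as.integer(d),
                spacing = as.double(pix[seq_len(3L)]))
  } else if (grepl("\\.uvol$", path)) {
    header <- scan(path, n = 6, quiet = TRUE)
    d <- as.integer(header[1:3])
    vals <- scan(path, skip = 1, quiet = TRUE)
    if (length(vals) != prod(d))
      stop(sprintf("%s: expected %d values, found %d", path, prod(d),
                   length(vals)))
    out <- list(values = vals, dim = d, spacing = header[4:6])
  } else {
    stop(sprintf("unrecognized volume format: %s (expected .nii, .nii.gz or .uvol)",
                 path))
  }
  if (clamp_negative && any(out$values < 0)) {
    warning(sprintf("%d negative voxel(s) clamped to zero", sum(out$values < 0)))
    out$values <- pmax(out$values, 0)
  }
  out
}

#' Write a 3D volume
#'
#' Writes a flattened volume as NIfTI (`.nii` / `.nii.gz`) with the grid's
#' voxel spacings in the header, or as the plain-text raw container
#' (`.uvol`): one header line `n1 n2 n3 dx dy dz` followed by the values in
#' x-fastest order at full double precision (`%.17g`, so the text round trip
#' is bit-exact).
#'
#' @param values Flattened length-`n` volume.
#' @param grid A [grid_spec()] object.
#' @param path Output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, grid, path) {
  check_scalar_field(grid, values, "volume")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- array(values, dim = c(grid$n1, grid$n2, grid$n3))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(grid$dx, grid$dy, grid$dz)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.uvol$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d %d %.17g %.17g %.17g",
                       grid$n1, grid$n2, grid$n3, grid$dx, grid$dy, grid$dz),
               con)
    writeLines(sprintf("%.17g", values), con)
  } else {
    stop(sprintf("unrecognized volume format: %s", path))
  }
  invisible(path)
}

#' Export pathlines as legacy VTK polydata
#'
#' Writes the pathlines as an ASCII legacy VTK file with one polyline per
#' seed and per-vertex `speed` and `peclet` point-data arrays (infinite
#' Peclet values are written as 1e30).
#'
#' @param pathlines A [trace_pathlines()] result.
#' @param path Output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk_pathlines <- function(pathlines, path) {
  paths <- pathlines$paths
  npts <- sum(vapply(paths, function(p) nrow(p$vertices), integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "transport pathlines", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", npts)), con)
  for (p in paths)
    writeLines(sprintf("%.10g %.10g %.10g",
                       p$vertices[, 1], p$vertices[, 2], p$vertices[, 3]), con)
  sizes <- vapply(paths, function(p) nrow(p$vertices), integer(1))
  writeLines(sprintf("LINES %d %d", length(paths), sum(sizes + 1L)), con)
  offset <- 0L
  for (s in sizes) {
    writeLines(paste(c(s, seq.int(offset, length.out = s)), collapse = " "),
               con)
    offset <- offset + s
  }
  writeLines(sprintf("POINT_DATA %d", npts), con)
  for (attr_name in c("speed", "peclet")) {
    writeLines(c(sprintf("SCALARS %s double 1", attr_name),
                 "LOOKUP_TABLE default"), con)
    vals <- unlist(lapply(paths, `[[`, attr_name))
    vals[!is.finite(vals)] <- 1e30
    writeLines(sprintf("%.10g", vals), con)
  }
  invisible(path)
}

#' Export velocity flux vectors
#'
#' Writes the per-seed displacement vectors either as CSV or as a legacy
#' VTK point set with a `flux` vector array, selected by the extension.
#'
#' @param flux A [flux_vectors()] data frame.
#' @param path Output `.csv` or `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_flux_vectors <- function(flux, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(flux, path, row.names = FALSE)
  } else if (grepl("\\.vtk$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "velocity flux vectors",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(flux))), con)
    writeLines(sprintf("%.10g %.10g %.10g", flux$x0, flux$y0, flux$z0), con)
    writeLines(c(sprintf("POINT_DATA %d", nrow(flux)),
                 "VECTORS flux double"), con)
    writeLines(sprintf("%.10g %.10g %.10g", flux$dx, flux$dy, flux$dz), con)
  } else {
    stop(sprintf("unrecognized flux format: %s", path))
  }
  invisible(path)
}

#' Write a cost history as CSV
#'
#' @param solution A [gauss_newton()] solution.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_cost_history <- function(solution, path) {
  utils::write.csv(solution$cost_history, path, row.names = FALSE)
  invisible(path)
}
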