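#' Dose and LET grids
#'
#' A `dose_grid` is a scalar voxel field on a phantom raster with a
#' mandatory unit tag and provenance metadata. Supported units:
#' `"Gy"` (total physical dose), `"Gy/fx"` (physical dose per fraction),
#' `"Gy(RBE)"` (RBE-weighted total dose) and `"keV/um"` (dose-averaged
#' LET). Arithmetic between grids with different unit tags is an error;
#' this guards against, for example, summing a physical and an
#' RBE-weighted map.
#'
#' @param values 3D numeric array (non-negative).
#' @param unit Unit tag string.
#' @param phantom The `phantom` the grid lives on (shape check only).
#' @param meta Named list of provenance metadata (plan id, scenario id,
#'   RBE model id, ...).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, unit, phantom = NULL, meta = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(values < 0, na.rm = TRUE)) abort("dose/LET values must be non-negative")
  if (!is.character(unit) || length(unit) != 1) abort("unit tag is mandatory")
  if (!is.null(phantom) && !identical(dim(values), phantom$dim)) {
    abort("grid shape does not match the phantom raster")
  }
  structure(list(values = values, unit = unit, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> [%s] %s, max %.3f, mean %.3f\n",
              x$unit, paste(dim(x$values), collapse = "x"),
              max(x$values), mean(x$values)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
Ops.dose_grid <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    if (inherits(e1, "dose_grid") && inherits(e2, "dose_grid")) {
      if (!identical(e1$unit, e2$unit)) {
        abort(sprintf("unit mismatch: cannot combine '%s' with '%s'",
                      e1$unit, e2$unit))
      }
      v <- get(.Generic)(e1$values, e2$values)
      return(dose_grid(pmax(v, 0), e1$unit, meta = e1$meta))
    }
  }
  if (.Generic == "*" && xor(inherits(e1, "dose_grid"), inherits(e2, "dose_grid"))) {
    g <- if (inherits(e1, "dose_grid")) e1 else e2
    s <- if (inherits(e1, "dose_grid")) e2 else e1
    return(dose_grid(g$values * s, g$unit, meta = g$meta))
  }
  abort(sprintf("operation '%s' is not defined for these dose_grid operands",
                .Generic))
}

#' Extract grid values
#' @param grid A `dose_grid`.
#' @param mask Optional logical mask; if supplied, returns the masked vector.
#' @return Array or vector of values.
#' @export
grid_values <- function(grid, mask = NULL) {
  if (is.null(mask)) grid$values else grid$values[mask]
}

#' Tidy a dose grid to a tibble
#'
#' @param x A `dose_grid`.
#' @param phantom Optional `phantom`; if supplied, world coordinates and a
#'   `structure` column (first matching structure) are added and voxels
#'   outside the external contour are dropped.
#' @param ... Unused.
#' @return A tibble with voxel indices, value and unit.
#' @method as_tibble dose_grid
#' @export
as_tibble.dose_grid <- function(x, phantom = NULL, ...) {
  d <- dim(x$values)
  idx <- arrayInd(seq_along(x$values), d)
  out <- tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    value = as.vector(x$values), unit = x$unit
  )
  if (!is.null(phantom)) {
    keep <- as.vector(phantom$structures$external)
    out <- out[keep, ]
  }
  out
}

#' Write a grid as NIfTI with a JSON sidecar carrying the unit tag
#' @param grid A `dose_grid`.
#' @param path Output path ending in `.nii.gz`.
#' @param voxel_mm Voxel size for the NIfTI header.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, voxel_mm = c(1, 1, 1)) {
  RNifti::writeNifti(RNifti::asNifti(grid$values, pixdim = voxel_mm), path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(unit = grid$unit, meta = grid$meta), side,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a grid written by [write_grid()]
#' @param path Path to the `.nii.gz` file.
#' @return A `dose_grid`.
#' @export
read_grid <- function(path) {
  v <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  dose_grid(array(as.numeric(v), dim(v)), side$unit,
            meta = as.list(side$meta))
}
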