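#' CT and PET volume containers
#'
#' Lightweight containers for co-registered 3D scalar grids. The value array
#' uses axis order (z, y, x), i.e. `values[z, y, x]`; `spacing_mm` and
#' `origin_mm` follow the same order. CT values are Hounsfield units in
#' \[-1024, 3071\]; PET values are standardized uptake values (SUV >= 0).
#'
#' @param values 3D numeric array, dim (nz, ny, nx).
#' @param spacing_mm per-axis voxel size in mm, length 3, (z, y, x).
#' @param origin_mm per-axis origin in mm (default 0).
#' @return an object of class `ct_volume` or `pet_volume`.
#' @export
ct_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  v <- new_volume(values, spacing_mm, origin_mm, "ct_volume")
  rng <- range(v$values)
  stop_if_not(rng[1] >= -1024 && rng[2] <= 3071,
              "CT values outside [-1024, 3071] HU (range %.1f..%.1f)",
              rng[1], rng[2])
  v
}

#' @rdname ct_volume
#' @export
pet_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  v <- new_volume(values, spacing_mm, origin_mm, "pet_volume")
  stop_if_not(min(v$values) >= 0, "SUV values must be non-negative")
  v
}

new_volume <- function(values, spacing_mm, origin_mm, class) {
  stop_if_not(is.array(values) && length(dim(values)) == 3,
              "values must be a 3D array")
  stop_if_not(length(spacing_mm) == 3 && all(spacing_mm > 0),
              "spacing_mm must be 3 positive values (z, y, x)")
  structure(list(values = values,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = c(class, "pc_volume"))
}

#' @export
print.pc_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x), spacing %.2f x %.2f x %.2f mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  value range: %.2f .. %.2f\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.pc_volume <- function(x) dim(x$values)

# voxel volume in cm^3
voxel_cm3 <- function(vol) prod(vol$spacing_mm) / 1000

check_congruent <- function(ct, pet) {
  stop_if_not(identical(dim(ct$values), dim(pet$values)),
              "CT and PET grids are not congruent")
  stop_if_not(isTRUE(all.equal(ct$spacing_mm, pet$spacing_mm)),
              "CT and PET voxel spacing differ")
  invisible(TRUE)
}
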