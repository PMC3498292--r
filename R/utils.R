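# Internal helpers shared across modules.

#' Wrap angles into the interval (-180, 180]
#'
#' Degrees are reduced modulo 360 so that the result lies in `(-180, 180]`,
#' the convention used for all torsions in this package. `NA` passes through.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into `(-180, 180]`.
#' @export
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
wrap_angle <- function(x) {
  y <- x %% 360
  y[!is.na(y) & y > 180] <- y[!is.na(y) & y > 180] - 360
  y
}

# Standard atomic masses (u) for protein heavy atoms plus hydrogen.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Row-wise Euclidean norm of an n x 3 matrix.
rownorm <- function(a) sqrt(rowSums(a * a))

# Normalise rows of an n x 3 matrix to unit length.
unit_rows <- function(a) a / rownorm(a)

`%||%` <- function(a, b) if (is.null(a)) b else a

datafile <- function(name) {
  path <- system.file("extdata", name, package = "pbflex")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}
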