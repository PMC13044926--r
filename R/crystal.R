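# Crystal description: unit cell, symmetry, orientation, thickness,
# sensitivity, target resolution; plus the synthetic fixture generator.

# Reciprocal-space orthogonalization matrix (Busing-Levy B): maps integer
# hkl to a Cartesian reciprocal vector in 1/Angstrom.
cell_to_B <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0), all(cell[4:6] > 0),
            all(cell[4:6] < 180))
  a <- cell[1]; b <- cell[2]; c_ <- cell[3]
  al <- .deg2rad(cell[4]); be <- .deg2rad(cell[5]); ga <- .deg2rad(cell[6])
  V <- a * b * c_ * sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                         2 * cos(al) * cos(be) * cos(ga))
  as_ <- b * c_ * sin(al) / V
  bs <- a * c_ * sin(be) / V
  cs <- a * b * sin(ga) / V
  cos_als <- (cos(be) * cos(ga) - cos(al)) / (sin(be) * sin(ga))
  cos_bes <- (cos(al) * cos(ga) - cos(be)) / (sin(al) * sin(ga))
  cos_gas <- (cos(al) * cos(be) - cos(ga)) / (sin(al) * sin(be))
  sin_bes <- sqrt(max(0, 1 - cos_bes^2))
  matrix(c(as_, bs * cos_gas, cs * cos_bes,
           0, bs * sqrt(max(0, 1 - cos_gas^2)), -cs * sin_bes * cos(al),
           0, 0, 1 / c_), nrow = 3, byrow = TRUE)
}

#' Construct a crystal sample
#'
#' @param cell Six unit-cell parameters: a, b, c (Angstrom), alpha, beta,
#'   gamma (degrees).
#' @param symmetry A point-group symbol, [point_group()],
#'   [arithmetic_class()] or [symmetry_candidates()] object.
#' @param orientation 3x3 orthonormal setting matrix (crystal Cartesian
#'   frame to lab frame at all-zero goniostat angles); default identity.
#' @param thickness_um Crystal thickness T along the rotation axis (um).
#' @param sensitivity Relative radiation sensitivity s (1.0 = average
#'   protein crystal).
#' @param target_resolution_A Target resolution d_min (Angstrom).
#' @return Object of class `"crystal_sample"`, with the reciprocal
#'   orthogonalization matrix in `$B`.
#' @export
crystal_sample <- function(cell, symmetry = "1", orientation = diag(3),
                           thickness_um = 12, sensitivity = 1.0,
                           target_resolution_A = 2.0) {
  stopifnot(thickness_um > 0, sensitivity > 0, target_resolution_A > 0)
  orientation <- as.matrix(orientation)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-8)
    stop("orientation matrix must be orthonormal", call. = FALSE)
  if (inherits(symmetry, "symmetry_candidates")) {
    cands <- symmetry
  } else if (inherits(symmetry, "arithmetic_class")) {
    cands <- symmetry_candidates(list(symmetry))
  } else {
    cands <- symmetry_candidates(list(arithmetic_class(symmetry)))
  }
  structure(list(cell = as.numeric(cell), symmetry = cands,
                 orientation = orientation, B = cell_to_B(cell),
                 thickness_um = thickness_um, sensitivity = sensitivity,
                 target_resolution_A = target_resolution_A),
            class = "crystal_sample")
}

#' @export
print.crystal_sample <- function(x, ...) {
  cat(sprintf("Crystal: cell %.2f %.2f %.2f / %.1f %.1f %.1f, PG %s, d_min %.2f A\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
              strategy_point_group(x)$name, x$target_resolution_A))
  invisible(x)
}

#' Point group a strategy is computed for
#'
#' Applies [select_strategy_symmetry()] to the sample's candidate list.
#' @param crystal A [crystal_sample()].
#' @return A [point_group()].
#' @export
strategy_point_group <- function(crystal) {
  select_strategy_symmetry(crystal$symmetry)$point_group
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

.fixture_pg <- c(triclinic = "1", monoclinic = "2", orthorhombic = "222",
                 tetragonal = "4", trigonal = "3", hexagonal = "6",
                 cubic = "23")

#' Generate a synthetic crystal fixture
#'
#' Draws a random unit cell in realistic macromolecular ranges respecting
#' the constraints of the requested crystal system (edges uniform in 25-60
#' Angstrom; free angles in 75-105 degrees, bounded away from 90; beta in
#' 95-115 for monoclinic), and a uniformly random orientation. Thickness
#' defaults to 12 um and sensitivity to 1.0 (an average protein crystal).
#'
#' @param system One of `"triclinic" "monoclinic" "orthorhombic"
#'   "tetragonal" "trigonal" "hexagonal" "cubic"`.
#' @param seed Optional integer seed for reproducible fixtures.
#' @param point_group Optional point-group symbol overriding the system
#'   default (must belong to the system's lattice).
#' @param target_resolution_A Target resolution (default 2.0).
#' @param cell_range Range for cell edges (Angstrom).
#' @param file Optional path; when given the crystal is also written as
#'   YAML via [write_crystal()].
#' @return A [crystal_sample()].
#' @export
generate_fixture <- function(system = c("triclinic", "monoclinic",
                                        "orthorhombic", "tetragonal",
                                        "trigonal", "hexagonal", "cubic"),
                             seed = NULL, point_group = NULL,
                             target_resolution_A = 2.0,
                             cell_range = c(25, 60), file = NULL) {
  system <- match.arg(system)
  if (!is.null(seed)) set.seed(seed)
  runit <- function(n = 1) stats::runif(n, cell_range[1], cell_range[2])
  rang <- function(n = 1) {  # angle away from 90 by at least 3 degrees
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    90 + sgn * stats::runif(n, 3, 15)
  }
  cell <- switch(system,
    triclinic = c(runit(3), rang(3)),
    monoclinic = c(runit(3), 90, stats::runif(1, 95, 115), 90),
    orthorhombic = c(runit(3), 90, 90, 90),
    tetragonal = {a <- runit(); c(a, a, runit(), 90, 90, 90)},
    trigonal = {a <- runit(); c(a, a, runit(), 90, 90, 120)},
    hexagonal = {a <- runit(); c(a, a, runit(), 90, 90, 120)},
    cubic = {a <- runit(); c(a, a, a, 90, 90, 90)})
  pg <- point_group %||% .fixture_pg[[system]]
  cr <- crystal_sample(cell, symmetry = pg, orientation = random_rotation(),
                       target_resolution_A = target_resolution_A)
  if (!is.null(file)) write_crystal(cr, file)
  cr
}
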