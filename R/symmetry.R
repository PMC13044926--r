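# Point-group algebra for the 11 axial (proper, non-centrosymmetric beyond
# rotations) point groups used in rotation-method strategy planning.
# Operators are integer matrices W acting on reflection indices as
# hkl' = hkl %*% W, in the conventional setting of each group (trigonal and
# hexagonal groups on hexagonal axes).

.pg_names <- c("1", "2", "3", "4", "6", "222", "32", "422", "622", "23", "432")

.pg_orders <- c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "6" = 6L,
                "222" = 4L, "32" = 6L, "422" = 8L, "622" = 12L,
                "23" = 12L, "432" = 24L)

.pg_system <- c("1" = "triclinic", "2" = "monoclinic", "3" = "trigonal",
                "4" = "tetragonal", "6" = "hexagonal", "222" = "orthorhombic",
                "32" = "trigonal", "422" = "tetragonal", "622" = "hexagonal",
                "23" = "cubic", "432" = "cubic")

# Highest rotation-axis order in the group; used as a "how symmetric" key.
.pg_max_axis <- c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "6" = 6L,
                  "222" = 2L, "32" = 3L, "422" = 4L, "622" = 6L,
                  "23" = 3L, "432" = 4L)

.mat3 <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)

# Generators: coordinate rotation matrices in the conventional basis
# (International Tables conventions; monoclinic b-unique, trigonal and
# hexagonal on hexagonal axes, 32 in both the 321 and 312 settings).
.pg_generators <- function(name, setting = NULL) {
  two_b <- .mat3(-1, 0, 0, 0, 1, 0, 0, 0, -1)
  two_x <- .mat3(1, 0, 0, 0, -1, 0, 0, 0, -1)
  two_z <- .mat3(-1, 0, 0, 0, -1, 0, 0, 0, 1)
  four_z <- .mat3(0, -1, 0, 1, 0, 0, 0, 0, 1)
  three_z_hex <- .mat3(0, -1, 0, 1, -1, 0, 0, 0, 1)
  six_z_hex <- .mat3(1, -1, 0, 1, 0, 0, 0, 0, 1)
  two_100_hex <- .mat3(1, -1, 0, 0, -1, 0, 0, 0, -1)   # twofold along a
  two_110_hex <- .mat3(0, -1, 0, -1, 0, 0, 0, 0, -1)   # twofold along [1-10]*
  three_111 <- .mat3(0, 0, 1, 1, 0, 0, 0, 1, 0)
  switch(name,
    "1" = list(diag(3)),
    "2" = list(two_b),
    "3" = list(three_z_hex),
    "4" = list(four_z),
    "6" = list(six_z_hex),
    "222" = list(two_z, two_x),
    "32" = if (identical(setting, "312")) list(three_z_hex, two_110_hex)
           else list(three_z_hex, two_100_hex),
    "422" = list(four_z, two_x),
    "622" = list(six_z_hex, two_100_hex),
    "23" = list(two_z, two_x, three_111),
    "432" = list(four_z, three_111),
    stop("unknown point group '", name, "'; supported groups: ",
         paste(.pg_names, collapse = ", "), call. = FALSE)
  )
}

.mat_key <- function(m) paste(as.integer(round(m)), collapse = ",")

.group_closure <- function(generators) {
  ops <- list()
  seen <- character()
  queue <- c(list(diag(3)), generators)
  while (length(queue) > 0) {
    m <- round(queue[[1]])
    queue <- queue[-1]
    key <- .mat_key(m)
    if (key %in% seen) next
    seen <- c(seen, key)
    ops[[length(ops) + 1L]] <- m
    for (g in generators) {
      queue[[length(queue) + 1L]] <- m %*% g
    }
    if (length(ops) > 48) stop("group closure did not terminate", call. = FALSE)
  }
  ops[order(vapply(ops, .mat_key, character(1)))]
}

#' Rotation operators of an axial point group
#'
#' Returns the proper rotation subgroup of one of the 11 axial point groups,
#' as integer matrices acting on reflection indices (`hkl' = hkl %*% W`) in
#' the conventional setting. Trigonal and hexagonal groups are given on
#' hexagonal axes; point group 32 exists in two arithmetic settings (321,
#' 312) that place the twofold axes differently in the lattice.
#'
#' @param name Point-group symbol, one of
#'   `"1" "2" "3" "4" "6" "222" "32" "422" "622" "23" "432"`.
#' @param setting For point group 32 only: `"321"` (default) or `"312"`.
#' @return A list of 3x3 integer matrices in a deterministic order.
#' @examples
#' length(point_group_operators("432"))  # 24
#' @export
point_group_operators <- function(name, setting = NULL) {
  name <- as.character(name)
  ops <- .group_closure(.pg_generators(name, setting))
  expected <- .pg_orders[[name]]
  stopifnot(length(ops) == expected)
  ops
}

#' Construct a point-group object
#'
#' @inheritParams point_group_operators
#' @return An object of class `"point_group"` with elements `name`,
#'   `operators`, `order` (number of proper rotations) and `laue_order`
#'   (order of the group generated by the rotations plus inversion; none of
#'   the 11 groups contains the inversion, so this is twice `order`).
#' @export
point_group <- function(name, setting = NULL) {
  name <- as.character(name)
  if (!name %in% .pg_names)
    stop("unknown point group '", name, "'; supported groups: ",
         paste(.pg_names, collapse = ", "), call. = FALSE)
  ops <- point_group_operators(name, setting)
  structure(list(name = name,
                 setting = if (name == "32") (setting %||% "321") else NULL,
                 operators = ops,
                 order = length(ops),
                 laue_order = 2L * length(ops),
                 system = .pg_system[[name]],
                 max_axis_order = .pg_max_axis[[name]]),
            class = "point_group")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.point_group <- function(x, ...) {
  cat("Point group", x$name,
      if (!is.null(x$setting)) paste0("(setting ", x$setting, ")"), "-",
      x$order, "rotations, Laue order", x$laue_order, "\n")
  invisible(x)
}

.make_pg <- function(name, setting = NULL) point_group(name, setting)

.as_point_group <- function(pg) {
  if (inherits(pg, "point_group")) pg else point_group(pg)
}

#' Symmetry-equivalent reflection indices
#'
#' Expands a reflection index triple to its orbit under the rotations of a
#' point group, optionally adding Friedel mates (the negatives of every
#' orbit member), which yields the orbit under the Laue group.
#'
#' @param hkl Integer vector of length 3.
#' @param pg A [point_group()] object or a point-group symbol.
#' @param friedel Logical; include Friedel mates (default `TRUE`).
#' @return An integer matrix with one equivalent per row, in lexicographic
#'   order without duplicates. The orbit size divides `2 * order` when
#'   `friedel` is set.
#' @examples
#' nrow(expand_equivalents(c(1, 2, 3), "432"))  # 48
#' @export
expand_equivalents <- function(hkl, pg, friedel = TRUE) {
  pg <- .as_point_group(pg)
  hkl <- as.integer(round(hkl))
  stopifnot(length(hkl) == 3)
  eq <- t(vapply(pg$operators, function(w) as.integer(hkl %*% w),
                 integer(3)))
  if (friedel) eq <- rbind(eq, -eq)
  eq <- unique(eq)
  eq[order(eq[, 1], eq[, 2], eq[, 3]), , drop = FALSE]
}

#' Construct an arithmetic crystal class
#'
#' A point group plus a lattice-centring letter and (for point group 32) an
#' axis setting. The centring must belong to the point group's crystal
#' system.
#'
#' @param point_group Point-group symbol or [point_group()] object.
#' @param centring One of `P A B C I F R`.
#' @param setting Axis setting for point group 32: `"321"` or `"312"`.
#' @return An object of class `"arithmetic_class"`.
#' @export
arithmetic_class <- function(point_group, centring = "P", setting = NULL) {
  pg <- .as_point_group(point_group)
  if (!is.null(setting) && pg$name == "32") pg <- .make_pg("32", setting)
  allowed <- switch(pg$system,
    triclinic = "P",
    monoclinic = c("P", "A", "B", "C", "I"),
    orthorhombic = c("P", "A", "B", "C", "I", "F"),
    tetragonal = c("P", "I"),
    trigonal = c("P", "R"),
    hexagonal = "P",
    cubic = c("P", "I", "F"))
  if (!centring %in% allowed)
    stop("centring '", centring, "' is not compatible with the ", pg$system,
         " system (allowed: ", paste(allowed, collapse = " "), ")",
         call. = FALSE)
  structure(list(point_group = pg, centring = centring,
                 setting = pg$setting),
            class = "arithmetic_class")
}

#' @export
print.arithmetic_class <- function(x, ...) {
  cat("Arithmetic crystal class", paste0(x$point_group$name, x$centring),
      if (!is.null(x$setting)) paste0("(setting ", x$setting, ")"), "\n")
  invisible(x)
}

.lattice_family <- function(system) {
  # trigonal (on hexagonal axes) and hexagonal groups share the hexagonal
  # Bravais lattice
  if (system %in% c("trigonal", "hexagonal")) "hexagonal" else system
}

# Can candidate point groups of these lattice families describe one
# indexing solution? Lower-symmetry groups are always admissible on a more
# symmetric (pseudo-symmetric) lattice; the hexagonal family is
# incompatible with the tetragonal and cubic ones.
.families_compatible <- function(fams) {
  fams <- unique(fams)
  if ("hexagonal" %in% fams &&
      any(c("tetragonal", "cubic") %in% fams)) return(FALSE)
  TRUE
}

#' Bundle candidate arithmetic crystal classes from one indexing solution
#'
#' @param classes A non-empty list of [arithmetic_class()] objects (or
#'   point-group symbols, taken as primitive classes) that share one Bravais
#'   lattice. Order is meaningful: it is the tie-break order used by
#'   [select_strategy_symmetry()].
#' @return An object of class `"symmetry_candidates"`.
#' @export
symmetry_candidates <- function(classes) {
  if (length(classes) == 0) stop("candidate list must be non-empty", call. = FALSE)
  classes <- lapply(classes, function(x) {
    if (inherits(x, "arithmetic_class")) x else arithmetic_class(x)
  })
  fams <- vapply(classes, function(x) .lattice_family(x$point_group$system),
                 character(1))
  if (!.families_compatible(fams))
    stop("candidate classes must share one Bravais lattice; got families: ",
         paste(unique(fams), collapse = ", "), call. = FALSE)
  structure(list(classes = classes), class = "symmetry_candidates")
}

#' Choose the symmetry a strategy is computed for
#'
#' Given candidate arithmetic crystal classes compatible with one indexing
#' solution, returns the class the strategy should assume: the lowest
#' symmetry above monoclinic, i.e. the candidate with the fewest rotation
#' operators among those of group order at least 3 (for a hexagonal lattice
#' offering 3, 6, 32 and 622 this selects 3). If every candidate is
#' triclinic or monoclinic, the lowest-order candidate is returned. Ties on
#' operator count are broken first toward the group with the lower maximal
#' rotation-axis order (222 over 4), then by list order; the applied
#' tie-break is recorded in the `"tie_break"` attribute.
#'
#' @param cands A [symmetry_candidates()] object (or list acceptable to it).
#' @return The selected [arithmetic_class()], with attribute `"tie_break"`.
#' @export
select_strategy_symmetry <- function(cands) {
  if (!inherits(cands, "symmetry_candidates")) cands <- symmetry_candidates(cands)
  cl <- cands$classes
  ord <- vapply(cl, function(x) x$point_group$order, integer(1))
  axis <- vapply(cl, function(x) x$point_group$max_axis_order, integer(1))
  pool <- which(ord >= 3)
  if (length(pool) == 0) pool <- seq_along(cl)
  o <- pool[order(ord[pool], axis[pool], seq_along(pool))]
  pick <- o[1]
  tie <- sum(ord[pool] == ord[pick]) > 1
  res <- cl[[pick]]
  attr(res, "tie_break") <-
    if (!tie) "none"
    else if (sum(ord[pool] == ord[pick] & axis[pool] == axis[pick]) > 1)
      "list-order" else "lower-axis-order"
  res
}
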