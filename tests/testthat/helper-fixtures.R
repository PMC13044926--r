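# Shared fixtures and helpers for the test suite. All fixtures are built in
# code with fixed seeds.

fix_crystal <- local({
  cache <- list()
  function(system, seed, pg = NULL, d = 2.0, range = c(25, 60)) {
    key <- paste(system, seed, pg %||% "", d, paste(range, collapse = "-"))
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_fixture(system, seed = seed, point_group = pg,
                                        target_resolution_A = d,
                                        cell_range = range)
    cache[[key]]
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# Anomalous completeness of a single sweep, merged under the proper
# rotations only, restricted to orbits outside an enlarged cusp volume
# sin X > sin theta / sin(theta_rule) (theta_rule = NULL uses the strict
# cusp). Used to validate minimum-sweep-length rules.
anom_completeness <- function(crystal, pg_name, axis, width, start = 0,
                              theta_rule_deg = NULL) {
  sw <- make_sweep(crystal, axis_crystal = axis, omega_start_deg = start,
                   width_deg = width)
  sim <- simulate_sweeps(crystal, sw, d_min = crystal$target_resolution_A)
  H <- as.matrix(sim$hkl[, c("h", "k", "l")])
  r0 <- t(sw$setting %*% (crystal$B %*% t(H)))
  len <- sqrt(rowSums(r0^2))
  X <- acos(pmin(1, pmax(-1, r0[, 1] / len)))
  th <- asin(len / 2)
  outside <- if (is.null(theta_rule_deg)) sin(X) > sin(th) + 1e-9 else
    sin(X) > sin(th) / sin(theta_rule_deg * pi / 180)
  measured <- tabulate(sim$observations$hkl_index, nbins = nrow(H)) > 0
  pg <- point_group(pg_name)
  # orbit ids under proper rotations via representative encoding
  K <- max(abs(H)) + 1L; M <- 2 * K + 1
  enc <- function(A) (A[, 1] + K) * M * M + (A[, 2] + K) * M + (A[, 3] + K)
  best <- NULL
  for (w in pg$operators) {
    code <- enc(H %*% w)
    best <- if (is.null(best)) code else pmax(best, code)
  }
  uid <- match(best, sort(unique(best)))
  umeas <- tapply(measured, uid, any)
  uout <- tapply(outside, uid, all)
  100 * mean(umeas[uout])
}

# Best completeness over a scan of omega starts (sweeps must start at
# omega values matched to the symmetry-axis directions; the planner scans).
anom_best_start <- function(crystal, pg_name, axis, width,
                            theta_rule_deg = NULL,
                            starts = seq(0, 175, by = 5)) {
  max(vapply(starts, function(s)
    anom_completeness(crystal, pg_name, axis, width, s, theta_rule_deg),
    numeric(1)))
}
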