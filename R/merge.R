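# Merging of simulated observations under a point group: per-unique
# multiplicity, completeness (non-anomalous and anomalous), S/N enhancement
# (sum of Lorentz factors over retained observations of an orbit) and
# equi-populated enhancement bins.

# Map each row of an integer index matrix H to a canonical orbit
# representative code under the point-group rotations (plus Friedel mates
# when requested). Returns a list with the code and the representative
# indices (the lexicographically largest orbit member).
.orbit_representatives <- function(H, pg, friedel = TRUE) {
  K <- max(abs(H)) + 1L
  M <- 2 * K + 1
  enc <- function(A) (A[, 1] + K) * M * M + (A[, 2] + K) * M + (A[, 3] + K)
  ops <- pg$operators
  best <- NULL; best_code <- NULL
  variants <- ops
  if (friedel) variants <- c(variants, lapply(ops, function(w) -w))
  for (w in variants) {
    A <- H %*% w
    code <- enc(A)
    if (is.null(best_code)) {
      best <- A; best_code <- code
    } else {
      upd <- code > best_code
      if (any(upd)) {
        best[upd, ] <- A[upd, , drop = FALSE]
        best_code[upd] <- code[upd]
      }
    }
  }
  list(code = best_code, rep = best)
}

#' Merge simulated observations under a point group
#'
#' Discards observations lost to gaps, shadows or the detector edge, maps
#' every reflection to its orbit representative and accumulates per-unique
#' multiplicity and S/N enhancement (the sum of Lorentz factors over
#' retained observations of the orbit, equal to multiplicity times the
#' average Lorentz enhancement). Completeness is reported relative to the
#' full unique set at the resolution limit, overall and outside the blind
#' region (orbits whose members are all blind never cross the Ewald sphere
#' and are excluded from the outside-blind denominator).
#'
#' @param sim A [simulate_sweeps()] result.
#' @param pg A [point_group()] or symbol; typically
#'   `strategy_point_group(crystal)`.
#' @param friedel Logical; merge Friedel mates (non-anomalous merging,
#'   default `TRUE`).
#' @param n_bins Number of equi-populated S/N enhancement bins (default 10).
#' @param use_gaps Apply the in-gap exclusion (default `TRUE` when the
#'   simulation carried a detector).
#' @return Object of class `"merged_stats"`: list with `unique` (one row
#'   per unique reflection: indices, multiplicity, mean and summed Lorentz,
#'   enhancement, blind/gap flags), `bins` (equi-populated enhancement bins
#'   with medians) and `summary`.
#' @export
merge_stats <- function(sim, pg, friedel = TRUE, n_bins = 10,
                        use_gaps = !is.null(sim$detector)) {
  pg <- .as_point_group(pg)
  H <- as.matrix(sim$hkl[, c("h", "k", "l")])
  if (nrow(H) == 0) {
    return(structure(list(unique = data.frame(), bins = data.frame(),
                          summary = list(n_unique = 0, completeness = 0,
                                         completeness_outside_blind = 0,
                                         anomalous_completeness = 0,
                                         max_multiplicity = 0,
                                         max_multiplicity_unaffected = 0,
                                         n_observations = 0)),
                     class = "merged_stats"))
  }
  orb <- .orbit_representatives(H, pg, friedel = friedel)
  code <- orb$code
  ucode <- sort(unique(code))
  uidx <- match(code, ucode)           # hkl row -> unique id
  nuniq <- length(ucode)
  first <- which(!duplicated(uidx))
  reps <- orb$rep[first, , drop = FALSE][order(uidx[first]), , drop = FALSE]

  # blindness per orbit: all/any over members and sweeps
  blind_any_hkl <- rowSums(sim$blind) > 0
  blind_all_hkl <- rowSums(!sim$blind) == 0
  orbit_fully_blind <- as.vector(tapply(blind_all_hkl, uidx, all))
  orbit_blind_affected <- as.vector(tapply(blind_any_hkl, uidx, any))

  obs <- sim$observations
  retained <- obs$on_detector & !obs$shadowed
  if (use_gaps) retained <- retained & !obs$in_gap
  obs <- obs[retained, , drop = FALSE]
  ou <- uidx[obs$hkl_index]
  mult <- tabulate(ou, nbins = nuniq)
  lsum <- numeric(nuniq)
  if (nrow(obs) > 0) {
    agg <- tapply(obs$lorentz, ou, sum)
    lsum[as.integer(names(agg))] <- as.numeric(agg)
  }
  gap_affected <- logical(nuniq)
  if (use_gaps && nrow(sim$observations) > 0) {
    gobs <- sim$observations
    gsel <- which(!is.na(gobs$in_gap) & gobs$in_gap)
    if (length(gsel) > 0)
      gap_affected[unique(uidx[gobs$hkl_index[gsel]])] <- TRUE
  }
  u <- data.frame(h = reps[, 1], k = reps[, 2], l = reps[, 3],
                  n_members = tabulate(uidx, nbins = nuniq),
                  multiplicity = mult, lorentz_sum = lsum,
                  lorentz_mean = ifelse(mult > 0, lsum / mult, NA),
                  enhancement = lsum,
                  fully_blind = orbit_fully_blind,
                  blind_affected = orbit_blind_affected,
                  gap_affected = gap_affected)

  measured <- mult > 0
  comp <- 100 * sum(measured) / nuniq
  outside <- !orbit_fully_blind
  comp_ob <- if (any(outside)) 100 * sum(measured & outside) / sum(outside) else 0

  # anomalous completeness: merge without Friedel pairing
  orb_a <- .orbit_representatives(H, pg, friedel = FALSE)
  ac <- orb_a$code
  auc <- sort(unique(ac))
  aidx <- match(ac, auc)
  a_blind_all <- as.vector(tapply(blind_all_hkl, aidx, all))
  a_meas <- logical(length(auc))
  if (nrow(obs) > 0) a_meas[unique(aidx[obs$hkl_index])] <- TRUE
  a_out <- !a_blind_all
  anom <- if (any(a_out)) 100 * sum(a_meas & a_out) / sum(a_out) else 0

  bins <- data.frame()
  meas_enh <- u$enhancement[measured]
  if (length(meas_enh) >= n_bins) {
    o <- order(meas_enh)
    grp <- ceiling(seq_along(o) / (length(o) / n_bins))
    med <- tapply(meas_enh[o], grp, stats::median)
    bins <- data.frame(bin = seq_len(n_bins),
                       n = as.integer(table(grp)),
                       median_enhancement = as.numeric(med))
  }
  unaffected <- !u$blind_affected & !u$gap_affected
  structure(list(unique = u, bins = bins,
                 summary = list(
                   n_unique = nuniq,
                   n_observations = nrow(obs),
                   completeness = comp,
                   completeness_outside_blind = comp_ob,
                   anomalous_completeness = anom,
                   max_multiplicity = if (nuniq > 0) max(mult) else 0,
                   max_multiplicity_unaffected =
                     if (any(unaffected)) max(mult[unaffected]) else 0,
                   mean_multiplicity = mean(mult),
                   redundancy_variance = stats::var(mult))),
            class = "merged_stats")
}

#' @export
print.merged_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Merged: %d unique, %d obs; completeness %.1f%% ",
                     "(%.1f%% outside blind), anomalous %.1f%%; ",
                     "multiplicity max %d (unaffected %d)\n"),
              s$n_unique, s$n_observations, s$completeness,
              s$completeness_outside_blind, s$anomalous_completeness,
              s$max_multiplicity, s$max_multiplicity_unaffected))
  invisible(x)
}
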