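# Binding-pocket openness: the Calpha-Calpha distance between the lower-lid
# lysine (610) and the upper-lid leucine (667) in author numbering, with a
# fixed width cutoff separating open from closed states.

# Internal: find the column triplet of one named atom.
atom_lookup <- function(topology, chain, resno, atom_name = "CA") {
  hit <- which(topology$chain == chain & topology$resno == resno &
                 topology$atom_name == atom_name)
  if (length(hit) != 1L) {
    stop("lookup error: atom ", atom_name, " of residue ", resno,
         " chain ", chain, if (length(hit) == 0L) " not found" else
           " is ambiguous")
  }
  topology$atom_index[hit]
}

#' Pocket width time series
#'
#' Per-frame Euclidean distance between the Calpha atoms of the two lid
#' residues (default 610 and 667). Distances are invariant under rigid
#' transforms, so no prior alignment is needed.
#'
#' @param frames A `frameset`.
#' @param monomer Chain identifier of the monomer.
#' @param residue_pair Two author residue numbers (default `c(610, 667)`).
#' @return A `pocket_series`: list with `monomer_id`, `times` (ns), `widths`
#'   (Angstrom) and `residue_pair`.
#' @export
pocket_width_series <- function(frames, monomer, residue_pair = c(610L, 667L)) {
  topo <- frames$topology
  i1 <- atom_lookup(topo, monomer, residue_pair[1L])
  i2 <- atom_lookup(topo, monomer, residue_pair[2L])
  c1 <- frames$xyz[, atom_cols(i1), drop = FALSE]
  c2 <- frames$xyz[, atom_cols(i2), drop = FALSE]
  w <- sqrt(rowSums((c1 - c2)^2))
  structure(list(monomer_id = monomer, times = frames$times, widths = w,
                 residue_pair = residue_pair),
            class = "pocket_series")
}

#' @export
print.pocket_series <- function(x, ...) {
  cat("pocket series (chain ", x$monomer_id, "): ", length(x$widths),
      " frames, width ", format(min(x$widths), digits = 3), "-",
      format(max(x$widths), digits = 3), " A\n", sep = "")
  invisible(x)
}

#' Centered moving average of a pocket series
#'
#' Averages over all frames whose time lies within +/- window/2 of each
#' frame's time; at the edges the window truncates. Smoothing is for
#' presentation only — state classification and occupancies operate on the
#' raw series.
#'
#' @param series A `pocket_series`.
#' @param window Window width in ns (> 0).
#' @return A smoothed `pocket_series` on the same times.
#' @export
moving_average <- function(series, window) {
  stopifnot(window > 0)
  t <- series$times
  half <- window / 2 + 1e-12
  lo <- findInterval(t - half, t) + 1L
  hi <- findInterval(t + half, t)
  cs <- c(0, cumsum(series$widths))
  out <- series
  out$widths <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Classify pocket frames as open or closed
#'
#' A frame is closed iff its width is strictly below the cutoff; a frame at
#' exactly the cutoff is open. The 11 Angstrom default separates the
#' pocket-open (15.5 A) and pocket-closed (9.4 A) reference conformations.
#'
#' @param series A `pocket_series` (raw, unsmoothed, by convention).
#' @param cutoff Width cutoff in Angstrom (default 11).
#' @return A `state_series`: list with `times`, `closed` (logical) and
#'   `cutoff`.
#' @export
classify_states <- function(series, cutoff = 11) {
  structure(list(times = series$times, closed = series$widths < cutoff,
                 cutoff = cutoff, monomer_id = series$monomer_id),
            class = "state_series")
}

# Internal: per-frame time weights (ns) — midpoint intervals, so irregular
# spacing is handled and the weights sum to the spanned duration.
frame_weights <- function(times) {
  T_ <- length(times)
  if (T_ == 1L) return(1)
  d <- diff(times)
  if (T_ == 2L) return(c(d / 2, d / 2))
  c(d[1L] / 2, (d[-1L] + d[-(T_ - 1L)]) / 2, d[T_ - 1L] / 2)
}

#' Pooled closed-state occupancy over replicate units
#'
#' Pools binary state series from all replicate units (one unit = one
#' monomer of one run), reporting the time-weighted fraction of closed
#' frames over all units together, plus the spread (standard deviation) of
#' the per-unit fractions. With 3 runs x 4 monomers x 1 us this is the
#' 12-unit, 12-us occupancy tabulation.
#'
#' @param state_series_set List of `state_series` (from [classify_states()]).
#' @param scenario Free-text label for the ligand-bonding scenario.
#' @param dispersion `"per_unit"` (default; std across all units) or
#'   `"per_run"` (std across run-level pooled fractions, requires `run_ids`).
#' @param run_ids Optional run label per series (for `"per_run"`).
#' @return An `occupancy_summary`: list with `scenario`, `fraction_closed`
#'   (percent), `dispersion` (percent), `n_units`, `total_time` (us).
#' @export
occupancy <- function(state_series_set, scenario = "",
                      dispersion = c("per_unit", "per_run"), run_ids = NULL) {
  dispersion <- match.arg(dispersion)
  if (length(state_series_set) == 0L) stop("empty input: no state series")
  closed_t <- numeric(length(state_series_set))
  total_t <- numeric(length(state_series_set))
  for (i in seq_along(state_series_set)) {
    s <- state_series_set[[i]]
    w <- frame_weights(s$times)
    closed_t[i] <- sum(w[s$closed])
    total_t[i] <- sum(w)
  }
  frac <- 100 * sum(closed_t) / sum(total_t)
  unit_frac <- 100 * closed_t / total_t
  if (dispersion == "per_run") {
    if (is.null(run_ids) || length(run_ids) != length(state_series_set)) {
      stop("per-run dispersion needs one run id per series")
    }
    run_closed <- tapply(closed_t, run_ids, sum)
    run_total <- tapply(total_t, run_ids, sum)
    unit_frac <- 100 * as.vector(run_closed / run_total)
  }
  disp <- if (length(unit_frac) > 1L) stats::sd(unit_frac) else 0
  structure(list(scenario = scenario, fraction_closed = frac,
                 dispersion = disp, n_units = length(state_series_set),
                 total_time = sum(total_t) / 1000),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf(
    "%s: population closed %.1f %%  (+/- %.1f over %d units, %.3g us total)\n",
    if (nzchar(x$scenario)) x$scenario else "occupancy",
    x$fraction_closed, x$dispersion, x$n_units, x$total_time))
  invisible(x)
}

#' Out-of-pocket ligand occupancy
#'
#' Fraction of trajectory time in which the ligand has rotated out of the
#' pocket: a frame counts as out when the minimum distance between any
#' ligand atom and any pocket-defining atom exceeds `contact_cutoff`.
#' Pocket-defining atoms are conventionally the heavy atoms of all residues
#' within 3.5 Angstrom of the ligand in the reference structure.
#'
#' @param frames A `frameset`.
#' @param ligand_selection,pocket_selection Non-empty `atom_selection`s.
#' @param contact_cutoff Distance cutoff in Angstrom (default 3.5).
#' @return Percent of time out of pocket (time-weighted).
#' @export
out_of_pocket_occupancy <- function(frames, ligand_selection,
                                    pocket_selection, contact_cutoff = 3.5) {
  if (length(ligand_selection$atom_indices) == 0L ||
      length(pocket_selection$atom_indices) == 0L) {
    stop("selection error: empty ligand or pocket selection")
  }
  T_ <- n_frames(frames)
  cl <- sel_cols(ligand_selection)
  cp <- sel_cols(pocket_selection)
  out <- logical(T_)
  for (t in seq_len(T_)) {
    L <- matrix(frames$xyz[t, cl], ncol = 3L, byrow = TRUE)
    P <- matrix(frames$xyz[t, cp], ncol = 3L, byrow = TRUE)
    d2min <- min(outer(rowSums(L^2), rowSums(P^2), "+") -
                   2 * tcrossprod(L, P))
    out[t] <- sqrt(max(d2min, 0)) > contact_cutoff
  }
  w <- frame_weights(frames$times)
  100 * sum(w[out]) / sum(w)
}

#' Pocket width of a single structure file
#'
#' Measures the lid Calpha-Calpha distance directly on a deposited (or
#' synthetic stand-in) coordinate file — the single-structure check
#' complementing the trajectory series.
#'
#' @param path PDB file.
#' @param chain Chain identifier.
#' @param residue_pair Two author residue numbers (default `c(610, 667)`).
#' @return Width in Angstrom.
#' @export
pocket_width_structure <- function(path, chain = "A",
                                   residue_pair = c(610L, 667L)) {
  topo <- read_topology(path)
  fs <- read_frames(path, topo)
  pocket_width_series(fs, chain, residue_pair)$widths[1L]
}

#' Write a pocket series (with states) as TSV
#'
#' @param series A `pocket_series`.
#' @param path Output path.
#' @param cutoff Classification cutoff in Angstrom.
#' @return `path`, invisibly.
#' @export
write_pocket_tsv <- function(series, path, cutoff = 11) {
  st <- classify_states(series, cutoff)
  utils::write.table(
    data.frame(time_ns = series$times, width_A = series$widths,
               state = ifelse(st$closed, "closed", "open")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
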