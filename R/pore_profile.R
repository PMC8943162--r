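# Probe-sphere pore profiling: at each slice along the channel axis, the
# radius of the largest sphere centred in that slice that overlaps no
# vdW-inflated atom, maximized over the slice plane (HOLE/CHAP family).

#' Van der Waals radius table
#'
#' Bondi-type radii in Angstrom for the common protein/ligand elements.
#' Unknown elements fall back to the carbon value (1.70 A).
#'
#' @return Named numeric vector, with a `"default"` entry.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, default = 1.70)
}

# Internal: per-atom vdW radius for a selection.
vdw_for_selection <- function(topology, selection, vdw) {
  el <- topology$element[selection$atom_indices + 1L]
  r <- unname(vdw[el])
  r[is.na(r)] <- vdw[["default"]]
  if (any(r <= 0)) stop("vdW radii must be positive")
  r
}

# Internal: probe radius at centre (x, y, z): clearance to the nearest
# vdW-inflated atom (3-D distances, so atoms off the slice still constrain).
slice_clearance <- function(xy, z, coords, radii) {
  dx <- coords[, 1L] - xy[1L]
  dy <- coords[, 2L] - xy[2L]
  dz <- coords[, 3L] - z
  min(sqrt(dx * dx + dy * dy + dz * dz) - radii)
}

# Internal: principal axis of a coordinate set (largest-variance direction).
principal_axis <- function(coords) {
  cc <- sweep(coords, 2L, colMeans(coords))
  e <- eigen(crossprod(cc) / nrow(coords), symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (v[3L] < 0) v <- -v
  v / sqrt(sum(v^2))
}

# Internal: rotation taking `axis` to +z.
axis_basis <- function(axis) {
  w <- axis / sqrt(sum(axis^2))
  a <- if (abs(w[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2L] * u[3L] - w[3L] * u[2L],
         w[3L] * u[1L] - w[1L] * u[3L],
         w[1L] * u[2L] - w[2L] * u[1L])
  rbind(u, v, w)   # rows: new x, y, z in old coordinates
}

#' Pore radius profile of a single frame
#'
#' Slices the structure perpendicular to the channel axis. At each slice
#' the profile radius is the maximum over the slice plane of the clearance
#' min_i(||pos_i - c|| - vdw_i), found by Nelder-Mead search seeded from the
#' previous slice's centre (first slice: the selection's geometric centre),
#' with a restart from the selection centre when the search caps or fails.
#' Negative clearances (blocked slice) report 0; clearances above
#' `max_probe` are capped and flagged.
#'
#' @param frames A `frameset` (the frame given by `frame` is profiled).
#' @param pore_selection `atom_selection` of pore-lining atoms.
#' @param frame Frame index (default 1).
#' @param axis Unit 3-vector of the channel axis, or NULL for the principal
#'   axis of the selection.
#' @param z_range Length-2 range along the axis in Angstrom, or NULL for the
#'   selection's extent.
#' @param z_step Slice spacing in Angstrom (default 0.5).
#' @param vdw Named radius table (see [vdw_radii()]).
#' @param max_probe Radius cap in Angstrom (default 10).
#' @return A `pore_profile`: list with `z` (A), `radii` (A), `centre`
#'   (n x 2 matrix of slice centres), `capped` (logical per slice),
#'   `min_radius`, `min_radius_z`, `axis`.
#' @export
pore_radius_profile <- function(frames, pore_selection, frame = 1L,
                                axis = NULL, z_range = NULL, z_step = 0.5,
                                vdw = vdw_radii(), max_probe = 10) {
  if (length(pore_selection$atom_indices) == 0L) {
    stop("selection error: empty pore selection")
  }
  stopifnot(z_step > 0)
  coords <- frame_coords(frames, frame)[pore_selection$atom_indices + 1L, ,
                                        drop = FALSE]
  radii <- vdw_for_selection(frames$topology, pore_selection, vdw)
  if (is.null(axis)) axis <- principal_axis(coords)
  B <- axis_basis(axis)
  rc <- coords %*% t(B)          # rotated so the axis is +z
  if (is.null(z_range)) z_range <- range(rc[, 3L])
  z_vals <- seq(z_range[1L], z_range[2L], by = z_step)
  centre0 <- colMeans(rc)[1:2]
  n <- length(z_vals)
  out_r <- numeric(n); out_c <- matrix(0, n, 2L); capped <- logical(n)
  seed <- centre0
  for (k in seq_len(n)) {
    z <- z_vals[k]
    obj <- function(xy) -slice_clearance(xy, z, rc, radii)
    fit <- stats::optim(seed, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 500L))
    best <- fit
    if (-fit$value >= max_probe || !identical(seed, centre0)) {
      fit2 <- stats::optim(centre0, obj, method = "Nelder-Mead",
                           control = list(reltol = 1e-10, maxit = 500L))
      if (fit2$value < best$value) best <- fit2
    }
    r <- -best$value
    if (r >= max_probe) {
      out_r[k] <- max_probe; capped[k] <- TRUE
    } else {
      out_r[k] <- max(r, 0)
    }
    out_c[k, ] <- best$par
    seed <- best$par
  }
  i_min <- which.min(out_r)
  structure(list(z = z_vals, radii = out_r, centre = out_c, capped = capped,
                 std = NULL, min_radius = out_r[i_min],
                 min_radius_z = z_vals[i_min], axis = axis),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore profile:", length(x$z), "slices, min radius",
      format(x$min_radius, digits = 3), "A at z =",
      format(x$min_radius_z, digits = 4), "A\n")
  invisible(x)
}

#' Minimum pore radius over time
#'
#' Profiles every frame (optionally strided) and reports the per-frame
#' minimum radius — the series used to judge whether the conduction pathway
#' stays open.
#'
#' @inheritParams pore_radius_profile
#' @param stride Profile every `stride`-th frame.
#' @return Data frame with `time_ns` and `min_radius_A`.
#' @export
min_radius_series <- function(frames, pore_selection, axis = NULL,
                              z_range = NULL, z_step = 0.5,
                              vdw = vdw_radii(), max_probe = 10,
                              stride = 1L) {
  idx <- seq.int(1L, n_frames(frames), by = stride)
  mins <- vapply(idx, function(t) {
    p <- tryCatch(
      pore_radius_profile(frames, pore_selection, frame = t, axis = axis,
                          z_range = z_range, z_step = z_step, vdw = vdw,
                          max_probe = max_probe),
      error = function(e) stop("frame ", t, ": ", conditionMessage(e)))
    p$min_radius
  }, numeric(1))
  data.frame(time_ns = frames$times[idx], min_radius_A = mins)
}

#' Average pore profile over frames
#'
#' Per-slice arithmetic mean and population standard deviation of a list of
#' profiles computed on a common z grid.
#'
#' @param profiles List of `pore_profile`s with identical `z`.
#' @return A `pore_profile` whose `radii` are per-z means, with `std` the
#'   per-z population standard deviation.
#' @export
average_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  z <- profiles[[1L]]$z
  for (p in profiles) {
    if (length(p$z) != length(z) || max(abs(p$z - z)) > 1e-9) {
      stop("grid mismatch: profiles must share a common z grid")
    }
  }
  R <- do.call(rbind, lapply(profiles, `[[`, "radii"))
  mu <- colMeans(R)
  sdev <- sqrt(colMeans(sweep(R, 2L, mu)^2))
  i_min <- which.min(mu)
  structure(list(z = z, radii = mu, centre = profiles[[1L]]$centre,
                 capped = Reduce(`|`, lapply(profiles, `[[`, "capped")),
                 std = sdev, min_radius = mu[i_min], min_radius_z = z[i_min],
                 axis = profiles[[1L]]$axis),
            class = "pore_profile")
}

#' Write a pore profile as TSV
#'
#' @param profile A `pore_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(z_A = profile$z, radius_A = profile$radii,
                   std_A = if (is.null(profile$std)) 0 else profile$std,
                   cx_A = profile$centre[, 1L], cy_A = profile$centre[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
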