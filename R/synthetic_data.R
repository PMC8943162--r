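# Synthetic fixtures with closed-form ground truth: every generator is a
# pure function of (spec, seed) so each analysis stage has an analytic
# oracle. These emulate stationary Gaussian heavy-atom fluctuations,
# Markov-switching pocket widths, and toy pore geometries; they do not
# emulate force-field dynamics, solvent or membrane.

# Internal: run code under a seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Internal: draw n samples from N(0, C) via the spectral square root
# (handles PSD-singular covariances; errors on indefinite input).
rmvn_psd <- function(n, C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  if (any(e$values < -tol)) {
    stop("spec error: covariance is not positive semi-definite")
  }
  lam <- pmax(e$values, 0)
  Z <- matrix(stats::rnorm(n * ncol(C)), n)
  Z %*% (t(e$vectors) * sqrt(lam))
}

#' Gaussian trajectory with a prescribed covariance
#'
#' Frames are the reference coordinates plus zero-mean multivariate-Gaussian
#' displacements with the given 3N x 3N covariance (coordinate order
#' x1,y1,z1,x2,...). The sample covariance converges to `covariance`, and
#' every entropy/MI computed from it converges to the corresponding
#' closed form — the oracle for the covariance/entropy/MI stack.
#'
#' @param topology A `topology` of N atoms.
#' @param reference_coords N x 3 matrix (Angstrom).
#' @param covariance 3N x 3N symmetric PSD matrix (Angstrom^2).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Frame spacing in ns (default 0.1).
#' @return A `frameset`.
#' @export
gen_gaussian_trajectory <- function(topology, reference_coords, covariance,
                                    n_frames, seed, dt = 0.1) {
  ref <- as.vector(t(as.matrix(reference_coords)))
  stopifnot(length(ref) == nrow(covariance), nrow(covariance) == ncol(covariance))
  X <- with_local_seed(seed, rmvn_psd(n_frames, covariance))
  xyz <- sweep(X, 2L, ref, "+")
  fs_build(xyz, (seq_len(n_frames) - 1L) * dt, topology)
}

#' Coupled pseudo-residue pair with analytic mutual information
#'
#' Two pseudo-residues whose first `d_per_block` matched coordinates share
#' correlation `rho` (coordinate m of A with coordinate m of B), all other
#' coordinates independent unit-variance. The population MI is exactly
#' -(d_per_block/2) ln(1 - rho^2) nats.
#'
#' @param rho Correlation of each matched coordinate pair, |rho| < 1.
#' @param d_per_block Number of matched coordinate pairs per residue.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Frame spacing in ns.
#' @return List with `frames` (a `frameset`; residues 1 and 2 on chain A,
#'   20 Angstrom apart), `analytic_mi` (nats), and the two selections
#'   `selection_a`, `selection_b`.
#' @export
gen_coupled_pair <- function(rho, d_per_block = 3L, n_frames, seed,
                             dt = 0.1) {
  if (abs(rho) >= 1) stop("spec error: |rho| must be < 1")
  stopifnot(d_per_block >= 1L)
  n_at <- as.integer(ceiling(d_per_block / 3))
  d_res <- 3L * n_at
  topo <- topology(
    atom_name = rep(paste0("C", seq_len(n_at)), 2L),
    resno = rep(1:2, each = n_at), resname = "GLY", chain = "A",
    element = "C")
  ref <- cbind(0, 0, rep(c(0, 20), each = n_at)) +
    cbind(seq_len(2L * n_at) * 1.5, 0, 0)
  C <- diag(2L * d_res)
  for (m in seq_len(d_per_block)) {
    C[m, d_res + m] <- rho
    C[d_res + m, m] <- rho
  }
  fs <- gen_gaussian_trajectory(topo, ref, C, n_frames, seed, dt)
  seg_a <- segment_def("resA", "A", 1L, 1L)
  seg_b <- segment_def("resB", "A", 2L, 2L)
  list(frames = fs,
       analytic_mi = -(d_per_block / 2) * log(1 - rho^2),
       selection_a = select_atoms(topo, seg_a),
       selection_b = select_atoms(topo, seg_b))
}

#' Markov-switching pocket-width series
#'
#' Two-state continuous-time Markov chain (open/closed) sampled on a regular
#' dt grid using the exact two-state transition probabilities, with the
#' observed width = state mean + Gaussian noise. The stationary closed
#' fraction is k_oc / (k_oc + k_co). State means default to the printed
#' pocket-open (15.5 A) and pocket-closed (9.4 A) reference widths.
#'
#' @param rate_open_to_closed,rate_closed_to_open Switching rates per ns.
#' @param mean_open,mean_closed State mean widths in Angstrom.
#' @param noise_sd Observation noise sd in Angstrom.
#' @param duration Series length in ns.
#' @param dt Sampling interval in ns (should be well below 1/max(rate)).
#' @param seed Integer seed.
#' @param monomer_id Chain label for the series.
#' @return List with `series` (a `pocket_series`), `states` (logical closed
#'   per frame) and `true_closed_fraction`.
#' @export
gen_markov_pocket <- function(rate_open_to_closed, rate_closed_to_open,
                              mean_open = 15.5, mean_closed = 9.4,
                              noise_sd = 0.5, duration = 1000, dt = 0.1,
                              seed = 1L, monomer_id = "A") {
  stopifnot(rate_open_to_closed >= 0, rate_closed_to_open >= 0,
            mean_open > 0, mean_closed > 0, dt > 0)
  k_oc <- rate_open_to_closed; k_co <- rate_closed_to_open
  ktot <- k_oc + k_co
  pi_closed <- if (ktot > 0) k_oc / ktot else 0
  T_ <- max(1L, as.integer(round(duration / dt)))
  # exact discrete-time transition probabilities of the 2-state CTMC
  decay <- if (ktot > 0) exp(-ktot * dt) else 1
  p_o_to_c <- pi_closed * (1 - decay)
  p_c_to_o <- (1 - pi_closed) * (1 - decay)
  res <- with_local_seed(seed, {
    closed <- logical(T_)
    closed[1L] <- stats::runif(1) < pi_closed
    u <- stats::runif(T_)
    for (t in seq_len(T_ - 1L)) {
      closed[t + 1L] <- if (closed[t]) u[t] >= p_c_to_o else u[t] < p_o_to_c
    }
    noise <- stats::rnorm(T_, 0, noise_sd)
    list(closed = closed, noise = noise)
  })
  widths <- ifelse(res$closed, mean_closed, mean_open) + res$noise
  series <- structure(list(monomer_id = monomer_id,
                           times = (seq_len(T_) - 1L) * dt,
                           widths = widths,
                           residue_pair = c(610L, 667L)),
                      class = "pocket_series")
  list(series = series, states = res$closed,
       true_closed_fraction = pi_closed)
}

#' Toy pore of stacked atom rings
#'
#' Rings of atoms centred on the z axis. At each ring's z the true maximal
#' probe radius is ring radius minus the element's vdW radius, giving an
#' analytic profile oracle. That closed form requires rings to be spaced
#' widely enough that no ring constrains another ring's slice
#' (r_j^2 + (z_i - z_j)^2 >= r_i^2 for all ring pairs); violations are
#' rejected so the returned truth is always exact.
#'
#' @param ring_radii Data frame (or 2-column matrix) with columns `z` and
#'   `radius` in Angstrom, one row per ring.
#' @param atoms_per_ring Atoms per ring (default 12).
#' @param element Element symbol for all atoms (default "C").
#' @param n_frames Replicate the static geometry over this many frames.
#' @param vdw Radius table used for the degeneracy check and truth.
#' @return List with `topology`, `frames`, `selection` (all atoms) and
#'   `true_profile` (data frame z, radius).
#' @export
gen_toy_pore <- function(ring_radii, atoms_per_ring = 12L, element = "C",
                         n_frames = 1L, vdw = vdw_radii()) {
  rr <- as.data.frame(ring_radii)
  if (is.null(rr$z)) names(rr) <- c("z", "radius")
  stopifnot(nrow(rr) >= 1L, atoms_per_ring >= 3L)
  r_el <- vdw[[toupper(element)]]
  if (is.null(r_el) || is.na(r_el)) r_el <- vdw[["default"]]
  if (any(rr$radius <= r_el)) {
    stop("degenerate pore: ring radius must exceed the vdW radius (",
         r_el, " A)")
  }
  for (i in seq_len(nrow(rr))) {
    lim <- rr$radius^2 + (rr$z - rr$z[i])^2
    if (any(lim[-i] < rr$radius[i]^2 - 1e-9)) {
      stop("rings too closely spaced: ring ", i,
           " is constrained by a neighbour, the ring-slice truth would ",
           "not hold")
    }
  }
  ang <- 2 * pi * (seq_len(atoms_per_ring) - 1L) / atoms_per_ring
  coords <- do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
    cbind(rr$radius[i] * cos(ang), rr$radius[i] * sin(ang), rr$z[i])
  }))
  n_at <- nrow(coords)
  topo <- topology(
    atom_name = paste0("C", rep(seq_len(atoms_per_ring), nrow(rr))),
    resno = rep(seq_len(nrow(rr)), each = atoms_per_ring),
    resname = "RNG", chain = "P", element = element)
  xyz <- matrix(rep(as.vector(t(coords)), n_frames), nrow = n_frames,
                byrow = TRUE)
  fs <- fs_build(xyz, seq_len(n_frames) - 1, topo)
  sel <- select_atoms(topo, segment_def("pore", "P", 1L, nrow(rr)))
  list(topology = topo, frames = fs, selection = sel,
       true_profile = data.frame(z = rr$z, radius = rr$radius - r_el))
}

# Internal: uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

#' Rigid-motion trajectory
#'
#' Each frame is the reference under an independent random proper rotation
#' and translation — internal geometry is exactly preserved, so after
#' superposition every frame must coincide with the reference.
#'
#' @param reference N x 3 coordinates (N >= 3).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param topology Optional `topology` (default: one CA pseudo-atom per row).
#' @param translation_sd Translation component sd in Angstrom.
#' @return A `frameset`.
#' @export
gen_rigid_motion <- function(reference, n_frames, seed, topology = NULL,
                             translation_sd = 5) {
  reference <- as.matrix(reference)
  stopifnot(nrow(reference) >= 3L)
  if (is.null(topology)) {
    topology <- channelmi::topology(
      atom_name = "CA", resno = seq_len(nrow(reference)), resname = "GLY",
      chain = "A", element = "C")
  }
  xyz <- with_local_seed(seed, {
    t(vapply(seq_len(n_frames), function(i) {
      R <- random_rotation()
      tr <- stats::rnorm(3, 0, translation_sd)
      as.vector(t(sweep(reference %*% t(R), 2L, tr, "+")))
    }, numeric(3L * nrow(reference))))
  })
  fs_build(xyz, seq_len(n_frames) - 1, topology)
}

#' TRPA1-like synthetic tetramer fixture
#'
#' Desk-scale stand-in for the channel's analysed region: four
#' pseudo-monomers (chains A-D), each carrying the four analysis segments
#' with the study's residue spans — pocket lid 663-676, S1 706-730, S4
#' 842-865, TRPL/S6 961-1005 — at 3 heavy backbone atoms (N, CA, C) per
#' residue. Atom fluctuations are independent isotropic Gaussians
#' (sd `fluct_sd`) except for one planted coupled residue pair per chain
#' (lid 671 and TRPL 988 by default): those two residues share a latent
#' mode of weight `coupling`, making them the strongest MI pair by
#' construction.
#'
#' @param n_frames Frames per trajectory.
#' @param seed Integer seed.
#' @param fluct_sd Per-coordinate fluctuation sd in Angstrom.
#' @param coupling Latent-mode weight (0 disables the planted pair).
#' @param coupled_pair Residue numbers of the planted pair
#'   (default `c(671, 988)`).
#' @param chains Chain labels (default A-D).
#' @param dt Frame spacing in ns.
#' @return List with `topology`, `frames`, `segments` (named list of
#'   per-chain `segment_def` lists), `coupled_pair`, and
#'   `analytic_mi` of the planted pair.
#' @export
gen_trpa1_like <- function(n_frames = 1500L, seed = 1L, fluct_sd = 0.5,
                           coupling = 1, coupled_pair = c(671L, 988L),
                           chains = c("A", "B", "C", "D"), dt = 0.1) {
  spans <- list(lid = c(663L, 676L), S1 = c(706L, 730L),
                S4 = c(842L, 865L), TRPL = c(961L, 1005L))
  atom_names <- c("N", "CA", "C")
  res_list <- list()
  for (ch in chains) {
    for (si in seq_along(spans)) {
      for (r in spans[[si]][1L]:spans[[si]][2L]) {
        res_list[[length(res_list) + 1L]] <-
          data.frame(chain = ch, resno = r, seg = names(spans)[si],
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, res_list)
  n_res <- nrow(res)
  topo <- topology(
    atom_name = rep(atom_names, n_res),
    resno = rep(res$resno, each = 3L),
    resname = "GLY",
    chain = rep(res$chain, each = 3L),
    element = rep(c("N", "C", "C"), n_res))
  n_at <- nrow(topo)
  # layout: chains on a 4-fold ring; within a chain, residues wind through a
  # compact ~20 A ball (three incommensurate frequencies), so the fit
  # selection spans the same spatial extent as the analysed atoms and
  # per-frame superposition jitter stays far below the fluctuation scale
  chain_angle <- (match(topo$chain, chains) - 1L) * pi / 2
  res_rank <- as.integer(factor(paste(topo$chain, topo$resno),
                                levels = unique(paste(topo$chain,
                                                      topo$resno))))
  ref <- cbind(25 * cos(chain_angle) + 10 * cos(0.7 * res_rank),
               25 * sin(chain_angle) + 10 * sin(0.7 * res_rank),
               10 * cos(1.3 * res_rank) + rep(c(0, 0.5, 1.0), n_res))
  fs_xyz <- with_local_seed(seed, {
    X <- matrix(stats::rnorm(n_frames * 3L * n_at, 0, fluct_sd), n_frames)
    if (coupling > 0) {
      for (ch in chains) {
        sel1 <- which(topo$chain == ch & topo$resno == coupled_pair[1L])
        sel2 <- which(topo$chain == ch & topo$resno == coupled_pair[2L])
        d1 <- atom_cols(sel1 - 1L); d2 <- atom_cols(sel2 - 1L)
        latent <- matrix(stats::rnorm(n_frames * length(d1), 0, fluct_sd),
                         n_frames)
        X[, d1] <- X[, d1] + coupling * latent
        X[, d2] <- X[, d2] + coupling * latent
      }
    }
    X
  })
  xyz <- sweep(fs_xyz, 2L, as.vector(t(ref)), "+")
  fs <- fs_build(xyz, (seq_len(n_frames) - 1L) * dt, topo)
  segments <- lapply(stats::setNames(chains, chains), function(ch) {
    lapply(stats::setNames(names(spans), names(spans)), function(s) {
      segment_def(s, ch, spans[[s]][1L], spans[[s]][2L])
    })
  })
  # planted-pair population MI: matched coords have variance s^2(1+c^2) and
  # cross-covariance s^2 c^2 -> rho = c^2/(1+c^2), 9 matched pairs
  rho <- coupling^2 / (1 + coupling^2)
  list(topology = topo, frames = fs, segments = segments,
       coupled_pair = coupled_pair,
       analytic_mi = -(9 / 2) * log(1 - rho^2))
}

#' Synthetic single-structure stand-ins for the pocket reference widths
#'
#' Writes a minimal synthetic PDB whose K610/L667 Calpha atoms sit at the
#' requested width — a stand-in for deposited reference coordinates used to
#' exercise the single-structure width check. It is constructed data, not
#' deposited data.
#'
#' @param path Output PDB path.
#' @param width Lid Calpha-Calpha distance in Angstrom (default 15.5, the
#'   pocket-open reference width; 9.4 for pocket-closed).
#' @param chain Chain label.
#' @return `path`, invisibly.
#' @export
write_synthetic_pocket_structure <- function(path, width = 15.5,
                                             chain = "A") {
  topo <- topology(atom_name = c("CA", "CA", "CA"),
                   resno = c(610L, 640L, 667L),
                   resname = c("LYS", "GLY", "LEU"),
                   chain = chain, element = "C")
  coords <- rbind(c(0, 0, 0), c(width / 2, 4, 0), c(width, 0, 0))
  fs <- fs_build(matrix(as.vector(t(coords)), 1L), 0, topo)
  write_frames_pdb(fs, path)
}
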