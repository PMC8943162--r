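#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `mobile` onto `reference`. The reflection branch of the SVD solution is
#' corrected so the returned rotation always has determinant +1; a mirror
#' image therefore superposes with nonzero residual rather than flipping
#' chirality.
#'
#' @param reference,mobile M x 3 coordinate matrices (Angstrom).
#' @param weights Optional M non-negative weights.
#' @return A `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3, Angstrom) and `rmsd` (Angstrom). The transform
#'   maps a mobile point x to `rotation %*% x + translation`.
#' @export
kabsch <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  m <- nrow(reference)
  stopifnot(ncol(reference) == 3L, ncol(mobile) == 3L, nrow(mobile) == m)
  if (m < 3L) stop("degeneracy error: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, m)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cr <- colSums(reference * w)
  cm <- colSums(mobile * w)
  P <- sweep(mobile, 2L, cm)      # centered mobile
  Q <- sweep(reference, 2L, cr)   # centered reference
  # collinearity check: centered point set must span a plane
  sv_ref <- svd(Q * sqrt(w), nu = 0L, nv = 0L)$d
  sv_mob <- svd(P * sqrt(w), nu = 0L, nv = 0L)$d
  if (sv_ref[2L] < 1e-10 * max(sv_ref[1L], 1e-30) ||
      sv_mob[2L] < 1e-10 * max(sv_mob[1L], 1e-30)) {
    stop("degeneracy error: collinear (or coincident) point set")
  }
  H <- crossprod(P * w, Q)        # 3 x 3 covariance of the pairing
  s <- svd(H)
  d_sign <- sign(det(s$v %*% t(s$u)))
  if (d_sign == 0) d_sign <- 1
  R <- s$v %*% diag(c(1, 1, d_sign)) %*% t(s$u)
  tr <- cr - as.vector(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `rigid_transform` from [kabsch()].
#' @param coords N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform: rmsd", format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Superpose every frame onto a reference
#'
#' Each frame is rigidly fitted (Kabsch) on the `fit_selection` atoms onto
#' the reference's selection coordinates, and the fitted transform is applied
#' to all atoms of the frame. This establishes the common reference framework
#' required before any coordinate-covariance computation; the usual fit
#' selection is the Calpha atoms of a structurally stable domain (the
#' TRP-like domain for per-monomer channel work).
#'
#' @param frames A `frameset`.
#' @param fit_selection An `atom_selection` used for the fit.
#' @param reference `"first"` (default) to fit onto frame 1, or an N x 3 (or
#'   M x 3, M = selection size) coordinate matrix of an external reference.
#' @return A new aligned `frameset` (times and topology unchanged).
#' @export
align_frameset <- function(frames, fit_selection, reference = "first") {
  cols <- sel_cols(fit_selection)
  m <- length(fit_selection$atom_indices)
  if (m < 3L) stop("degeneracy error: fit selection has fewer than 3 atoms")
  if (is.character(reference) && identical(reference, "first")) {
    ref <- matrix(frames$xyz[1L, cols], ncol = 3L, byrow = TRUE)
  } else {
    ref <- as.matrix(reference)
    if (nrow(ref) == n_atoms(frames) && nrow(ref) != m) {
      ref <- ref[fit_selection$atom_indices + 1L, , drop = FALSE]
    }
    if (nrow(ref) != m) {
      stop("external reference must have N or selection-size rows")
    }
  }
  out <- frames$xyz
  T_ <- n_frames(frames)
  for (t in seq_len(T_)) {
    mob <- matrix(frames$xyz[t, cols], ncol = 3L, byrow = TRUE)
    tr <- tryCatch(kabsch(ref, mob),
                   error = function(e) stop("frame ", t, ": ",
                                            conditionMessage(e)))
    allc <- matrix(frames$xyz[t, ], ncol = 3L, byrow = TRUE)
    out[t, ] <- as.vector(t(apply_transform(tr, allc)))
  }
  fs_build(out, frames$times, frames$topology)
}

#' Per-frame RMSD of a selection against a reference frame
#'
#' @param frames A `frameset`.
#' @param selection An `atom_selection`; default all atoms.
#' @param ref_frame Reference frame index (1-based).
#' @return Numeric vector of length T (Angstrom).
#' @export
frame_rmsd <- function(frames, selection = NULL, ref_frame = 1L) {
  cols <- if (is.null(selection)) seq_len(ncol(frames$xyz)) else
    sel_cols(selection)
  ref <- frames$xyz[ref_frame, cols]
  d2 <- sweep(frames$xyz[, cols, drop = FALSE], 2L, ref)
  sqrt(rowSums(d2^2) / (length(cols) / 3L))
}
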