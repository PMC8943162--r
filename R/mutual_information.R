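#' Trajectory coordinate covariance
#'
#' Covariance of the Cartesian coordinates of a selection across frames:
#' entry (ij, kl) is the trajectory average of the product of coordinate j of
#' atom i and coordinate l of atom k, minus the product of the individual
#' averages. Plain trajectory averages use denominator T (population form);
#' the T-1 sample form is available via `denominator`.
#'
#' Frames must already share a reference frame (see [align_frameset()]):
#' covariance of unaligned coordinates mixes internal motion with global
#' rigid-body drift.
#'
#' @param frames An aligned `frameset` with T >= 2.
#' @param selection An `atom_selection` of n atoms (d = 3n coordinates).
#' @param denominator `"T"` (default) or `"T-1"`.
#' @return A `coord_covariance`: list with `atom_indices`, `mean` (length d,
#'   Angstrom), `matrix` (d x d, Angstrom^2, symmetric PSD), `n_frames`.
#' @export
traj_covariance <- function(frames, selection, denominator = c("T", "T-1")) {
  denominator <- match.arg(denominator)
  T_ <- n_frames(frames)
  if (T_ < 2L) stop("insufficient frames: covariance needs T >= 2")
  X <- frames$xyz[, sel_cols(selection), drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  denom <- if (denominator == "T") T_ else T_ - 1L
  C <- crossprod(Xc) / denom
  C <- (C + t(C)) / 2
  structure(list(atom_indices = selection$atom_indices, mean = mu,
                 matrix = C, n_frames = T_),
            class = "coord_covariance")
}

# Internal: Gaussian configurational entropy of a covariance matrix via its
# spectrum, with an eigenvalue floor guarding singular directions.
entropy_from_matrix <- function(C, eigenvalue_floor) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(ev), 1)
  if (any(ev < -tol)) {
    stop("invalid covariance: negative eigenvalue ", format(min(ev)))
  }
  floored <- any(ev < eigenvalue_floor)
  ev <- pmax(ev, eigenvalue_floor)
  list(value = 0.5 * sum(log(2 * pi * exp(1) * ev)),
       dimension = length(ev), floor_applied = floored)
}

#' Quasi-harmonic configurational entropy
#'
#' Gaussian-approximation entropy H = 1/2 ln |2*pi*e*C| of a coordinate set,
#' computed from the eigenvalues of the covariance matrix (never a raw
#' determinant): H = 1/2 sum_k ln(2*pi*e*lambda_k). Eigenvalues below
#' `eigenvalue_floor` are raised to it, since the log-determinant diverges at
#' zero; `floor_applied` reports when this happened. Units are nats, with
#' coordinates in Angstrom.
#'
#' @param cov A `coord_covariance` or a plain symmetric PSD matrix
#'   (Angstrom^2).
#' @param eigenvalue_floor Minimum eigenvalue in Angstrom^2 (default 1e-8).
#' @return An `entropy_value`: list with `value` (nats), `dimension`,
#'   `floor_applied`.
#' @export
config_entropy <- function(cov, eigenvalue_floor = 1e-8) {
  C <- if (inherits(cov, "coord_covariance")) cov$matrix else as.matrix(cov)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(abs(C), 1)) {
    stop("invalid covariance: matrix must be square symmetric")
  }
  structure(entropy_from_matrix((C + t(C)) / 2, eigenvalue_floor),
            class = "entropy_value")
}

#' @export
print.entropy_value <- function(x, ...) {
  cat("configurational entropy:", format(x$value, digits = 6), "nats (d =",
      x$dimension, if (x$floor_applied) ", eigenvalue floor applied" else "",
      ")\n")
  invisible(x)
}

#' Gaussian mutual information between two atom selections
#'
#' MI(A, B) = H(A) + H(B) - H(A,B), all three configurational entropies
#' estimated from the same frames with the same eigenvalue floor. For
#' Gaussian fluctuations this equals 1/2 ln(|C_A||C_B|/|C_AB|) and is
#' non-negative for any PSD joint covariance; small negative values from the
#' floor are clipped to zero when `clip` is TRUE.
#'
#' @param frames An aligned `frameset` (T >= 2).
#' @param selection_a,selection_b Disjoint `atom_selection`s.
#' @param eigenvalue_floor Eigenvalue floor in Angstrom^2.
#' @param clip Clip negative estimates to 0 (default TRUE).
#' @return MI in nats (scalar), with attribute `floor_applied`.
#' @export
pairwise_mi <- function(frames, selection_a, selection_b,
                        eigenvalue_floor = 1e-8, clip = TRUE) {
  if (length(intersect(selection_a$atom_indices,
                       selection_b$atom_indices)) > 0L) {
    stop("selection error: selections overlap")
  }
  T_ <- n_frames(frames)
  if (T_ < 2L) stop("insufficient frames: MI needs T >= 2")
  ia <- selection_a$atom_indices
  ib <- selection_b$atom_indices
  # canonical block order (lowest atom index first): MI is symmetric, and
  # computing both orders through the identical arithmetic keeps
  # pairwise_mi(A, B) == pairwise_mi(B, A) bitwise
  if (min(ib) < min(ia)) { tmp <- ia; ia <- ib; ib <- tmp }
  cols <- c(atom_cols(ia), atom_cols(ib))
  X <- frames$xyz[, cols, drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  C <- crossprod(Xc) / T_
  C <- (C + t(C)) / 2
  da <- 3L * length(ia)
  mi_from_joint(C, da, eigenvalue_floor, clip)
}

# Internal: MI from a joint covariance with the A block first.
mi_from_joint <- function(C, da, eigenvalue_floor, clip = TRUE) {
  d <- nrow(C)
  ha <- entropy_from_matrix(C[seq_len(da), seq_len(da), drop = FALSE],
                            eigenvalue_floor)
  hb <- entropy_from_matrix(C[(da + 1L):d, (da + 1L):d, drop = FALSE],
                            eigenvalue_floor)
  hab <- entropy_from_matrix(C, eigenvalue_floor)
  mi <- ha$value + hb$value - hab$value
  if (clip) mi <- max(mi, 0)
  attr(mi, "floor_applied") <- ha$floor_applied || hb$floor_applied ||
    hab$floor_applied
  mi
}

# Internal: heavy-atom residue groups of a segment present in the topology.
residue_groups <- function(topology, segment, heavy_only = TRUE) {
  keep <- topology$chain == segment$chain &
    topology$resno >= segment$first_residue &
    topology$resno <= segment$last_residue
  if (heavy_only) keep <- keep & topology$is_heavy
  sub <- topology[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("segment '", segment$name, "' resolves to an empty selection")
  }
  split(sub, sub$resno)
}

#' Residue-pair mutual-information matrix
#'
#' Computes Gaussian MI for every inter-segment residue pair, each residue
#' represented by all of its heavy atoms. One full covariance over the union
#' of atoms is estimated once; each pair's three entropies are then read from
#' the corresponding sub-blocks, so all values share frames, alignment and
#' floor.
#'
#' @param frames An aligned `frameset`.
#' @param segments List of `segment_def`s (same chain for a per-monomer run).
#' @param heavy_only Use heavy atoms only (default TRUE).
#' @param eigenvalue_floor Eigenvalue floor in Angstrom^2.
#' @param include_intra Also compute pairs within a segment (default FALSE).
#' @param run_id,monomer_id Optional provenance labels stored with every
#'   value (used by [aggregate_max()]).
#' @return An `mi_matrix`: data frame with one row per unordered residue
#'   pair; columns chainA/resnoA/resnameA/segmentA, likewise for B, `mi_nats`,
#'   `floor_applied`, `src_run`, `src_monomer`.
#' @export
mi_matrix <- function(frames, segments, heavy_only = TRUE,
                      eigenvalue_floor = 1e-8, include_intra = FALSE,
                      run_id = NA_character_, monomer_id = NA_character_) {
  topo <- frames$topology
  groups <- list()
  seg_of <- character(0)
  for (s in segments) {
    g <- residue_groups(topo, s, heavy_only)
    names(g) <- paste0(s$name, ":", names(g))
    groups <- c(groups, g)
    seg_of <- c(seg_of, rep(s$name, length(g)))
  }
  n_res <- length(groups)
  cols_of <- lapply(groups, function(g) atom_cols(g$atom_index))
  all_cols <- unlist(cols_of, use.names = FALSE)
  if (anyDuplicated(all_cols)) {
    stop("selection error: segments overlap in atoms")
  }
  # position of each residue's coordinates inside the pooled matrix
  offs <- cumsum(c(0L, lengths(cols_of)))
  pos_of <- lapply(seq_len(n_res),
                   function(r) (offs[r] + 1L):offs[r + 1L])
  T_ <- n_frames(frames)
  if (T_ < 2L) stop("insufficient frames: MI needs T >= 2")
  X <- frames$xyz[, all_cols, drop = FALSE]
  Xc <- sweep(X, 2L, colMeans(X))
  C <- crossprod(Xc) / T_
  C <- (C + t(C)) / 2
  ent <- vector("list", n_res)
  for (r in seq_len(n_res)) {
    ent[[r]] <- entropy_from_matrix(C[pos_of[[r]], pos_of[[r]],
                                      drop = FALSE], eigenvalue_floor)
  }
  pair_idx <- which(upper.tri(matrix(0, n_res, n_res)), arr.ind = TRUE)
  if (!include_intra) {
    pair_idx <- pair_idx[seg_of[pair_idx[, 1L]] != seg_of[pair_idx[, 2L]], ,
                         drop = FALSE]
  }
  n_pairs <- nrow(pair_idx)
  if (n_pairs == 0L) stop("no residue pairs to evaluate")
  mi <- numeric(n_pairs)
  floored <- logical(n_pairs)
  for (k in seq_len(n_pairs)) {
    r1 <- pair_idx[k, 1L]; r2 <- pair_idx[k, 2L]
    p <- c(pos_of[[r1]], pos_of[[r2]])
    hab <- entropy_from_matrix(C[p, p, drop = FALSE], eigenvalue_floor)
    mi[k] <- max(ent[[r1]]$value + ent[[r2]]$value - hab$value, 0)
    floored[k] <- ent[[r1]]$floor_applied || ent[[r2]]$floor_applied ||
      hab$floor_applied
  }
  meta <- function(f) vapply(groups, function(g) f(g)[1L], f(groups[[1L]])[1L])
  ch <- meta(function(g) g$chain)
  rn <- meta(function(g) g$resno)
  rs <- meta(function(g) g$resname)
  i1 <- pair_idx[, 1L]; i2 <- pair_idx[, 2L]
  out <- data.frame(
    chainA = ch[i1], resnoA = rn[i1], resnameA = rs[i1], segmentA = seg_of[i1],
    chainB = ch[i2], resnoB = rn[i2], resnameB = rs[i2], segmentB = seg_of[i2],
    mi_nats = mi, floor_applied = floored,
    src_run = run_id, src_monomer = monomer_id,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("mi_matrix", "data.frame")
  out
}

# Internal: monomer-independent residue-pair key.
mi_pair_key <- function(m) {
  paste(m$segmentA, m$resnoA, m$segmentB, m$resnoB, sep = "\r")
}

#' Entrywise maximum of MI matrices over runs and monomers
#'
#' Pools replicate estimates of the same residue-pair index (residue pairs
#' are matched by segment and residue number, so the four monomers of a
#' homotetramer and all repeat runs are comparable) by taking, for each pair,
#' the maximum MI over all inputs, recording which (run, monomer) supplied
#' it.
#'
#' @param matrices List of `mi_matrix` objects sharing the residue-pair
#'   index (chains may differ).
#' @return An `mi_matrix` with provenance columns `src_run`, `src_monomer`
#'   filled from the arg-max input.
#' @export
aggregate_max <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  keys <- lapply(matrices, mi_pair_key)
  ref <- keys[[1L]]
  for (i in seq_along(keys)) {
    if (length(keys[[i]]) != length(ref) ||
        !setequal(keys[[i]], ref) || anyDuplicated(keys[[i]])) {
      stop("aggregation error: residue-pair index mismatch in matrix ", i)
    }
  }
  out <- matrices[[1L]]
  out <- out[order(mi_pair_key(out)), , drop = FALSE]
  best <- out$mi_nats
  for (i in seq_along(matrices)[-1L]) {
    m <- matrices[[i]][order(keys[[i]]), , drop = FALSE]
    better <- m$mi_nats > best
    if (any(better)) {
      out[better, ] <- m[better, , drop = FALSE]
      best[better] <- m$mi_nats[better]
    }
  }
  out <- out[order(out$segmentA, out$resnoA, out$segmentB, out$resnoB), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mi_matrix", "data.frame")
  out
}

#' Segment-pair coupling summary
#'
#' For a pair of segments, takes each residue's maximum MI to any residue of
#' the partner segment, over the residues of both segments, and reports the
#' arithmetic mean of those per-residue maxima. Applied to an
#' [aggregate_max()] matrix this is the segment-level coupling score used to
#' judge which inter-domain contacts stand out.
#'
#' @param max_matrix An `mi_matrix` (typically aggregated).
#' @param segment_a,segment_b Segment names or `segment_def`s.
#' @return A `segment_pair_summary`: list with `segmentA`, `segmentB`,
#'   `per_residue_max` (named nats vector, names `segment:resno`) and
#'   `mean_of_maxima`.
#' @export
segment_pair_mean <- function(max_matrix, segment_a, segment_b) {
  na <- if (inherits(segment_a, "segment_def")) segment_a$name else segment_a
  nb <- if (inherits(segment_b, "segment_def")) segment_b$name else segment_b
  fwd <- max_matrix$segmentA == na & max_matrix$segmentB == nb
  rev <- max_matrix$segmentA == nb & max_matrix$segmentB == na
  m <- max_matrix[fwd | rev, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("no residue pairs between segments '", na, "' and '", nb, "'")
  }
  res_a <- ifelse(m$segmentA == na, m$resnoA, m$resnoB)
  res_b <- ifelse(m$segmentA == na, m$resnoB, m$resnoA)
  max_a <- tapply(m$mi_nats, res_a, max)
  max_b <- tapply(m$mi_nats, res_b, max)
  per_res <- c(stats::setNames(as.vector(max_a),
                               paste0(na, ":", names(max_a))),
               stats::setNames(as.vector(max_b),
                               paste0(nb, ":", names(max_b))))
  structure(list(segmentA = na, segmentB = nb, per_residue_max = per_res,
                 mean_of_maxima = mean(per_res)),
            class = "segment_pair_summary")
}

#' @export
print.segment_pair_summary <- function(x, ...) {
  cat("segments", x$segmentA, "--", x$segmentB, ": mean residue-pair maximum",
      format(x$mean_of_maxima, digits = 4), "nats over",
      length(x$per_residue_max), "residues\n")
  invisible(x)
}

#' Strongest-coupling residue pairs
#'
#' Ranks residue pairs by MI (descending), ties broken by residue number of
#' A then B, filtered at `min_value`; the head of this list is the edge list
#' of the coupling-pathway graph.
#'
#' @param max_matrix An `mi_matrix`.
#' @param k Maximum number of pairs to return.
#' @param min_value Discard pairs below this MI (nats).
#' @return An `mi_matrix` of at most `k` rows in rank order.
#' @export
top_pairs <- function(max_matrix, k, min_value = 0) {
  stopifnot(k >= 1L)
  m <- max_matrix[max_matrix$mi_nats >= min_value, , drop = FALSE]
  m <- m[order(-m$mi_nats, m$resnoA, m$resnoB), , drop = FALSE]
  m <- utils::head(m, k)
  rownames(m) <- NULL
  class(m) <- c("mi_matrix", "data.frame")
  m
}

#' Shuffled-frames MI null distribution
#'
#' Destroys the temporal pairing between two selections by permuting the
#' frame order of B independently of A, and recomputes MI for each
#' permutation. The resulting distribution is the finite-sample bias floor
#' of the Gaussian MI estimator under independence.
#'
#' @inheritParams pairwise_mi
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null MI values (nats).
#' @export
mi_shuffle_null <- function(frames, selection_a, selection_b, n_perm = 100L,
                            eigenvalue_floor = 1e-8, seed = 1L) {
  T_ <- n_frames(frames)
  ca <- sel_cols(selection_a)
  cb <- sel_cols(selection_b)
  A <- frames$xyz[, ca, drop = FALSE]
  B <- frames$xyz[, cb, drop = FALSE]
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      Bp <- B[sample.int(T_), , drop = FALSE]
      C <- crossprod(cbind(A, Bp)) / T_
      as.numeric(mi_from_joint((C + t(C)) / 2, ncol(A), eigenvalue_floor))
    }, numeric(1))
  })
}

#' Write an MI matrix as tidy TSV
#'
#' @param m An `mi_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mi_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
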