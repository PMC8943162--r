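# Internal: magic bytes identifying the packed binary frame container.
.frames_magic <- charToRaw("CMI1")

# Internal: single-conformer altloc resolution shared by the topology and
# frame readers — highest occupancy wins, ties -> first encountered.
altloc_keep <- function(at) {
  alt <- at$alt
  has_alt <- !is.na(alt) & nzchar(trimws(alt))
  keep <- rep(TRUE, nrow(at))
  if (!any(has_alt)) return(keep)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) > 1L) {
      best <- rows[which.max(occ[rows])]
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  keep
}

#' Read a topology from a PDB file
#'
#' Builds the frame-independent atom skeleton (residue identities, chains,
#' elements, heavy-atom flags) from the first MODEL of a PDB file. Both ATOM
#' and HETATM records are retained, so covalently docked ligand adducts stay
#' addressable; downstream residue selections are protein-range based and do
#' not pick them up unless asked.
#'
#' Alternate locations are resolved to a single conformer by keeping the
#' highest-occupancy altloc (ties broken by file order). Records carrying
#' insertion codes are rejected: author residue numbering must be unambiguous
#' because residues are addressed by number throughout (e.g. K610, L667).
#'
#' @param path Path to a PDB file.
#' @return A `topology` object: a data frame with one row per atom and columns
#'   `atom_index` (0-based, contiguous), `atom_name`, `resno` (author
#'   numbering), `resname`, `chain`, `element`, `is_heavy`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) {
    stop("topology file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("unparsable PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty input: no ATOM/HETATM records in ", path)
  }
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    bad <- which(!is.na(ins) & nzchar(trimws(ins)))[1L]
    stop("insertion codes are not supported (record ", bad,
         ", residue ", at$resno[bad], at$insert[bad], ")")
  }
  at <- at[altloc_keep(at), , drop = FALSE]
  element <- trimws(at$elesy)
  missing_el <- is.na(element) | !nzchar(element)
  if (any(missing_el)) {
    # fall back to the atom-name convention via bio3d's lookup
    element[missing_el] <- vapply(at$elety[missing_el], function(nm) {
      tryCatch(bio3d::atom2ele(nm), error = function(e) NA_character_)
    }, character(1))
  }
  if (anyNA(element)) {
    bad <- which(is.na(element))[1L]
    stop("format error at record ", bad, ": cannot infer element for atom '",
         at$elety[bad], "'")
  }
  element <- toupper(element)
  chain <- at$chain
  chain[is.na(chain)] <- " "
  topo <- data.frame(
    atom_index = seq_len(nrow(at)) - 1L,
    atom_name  = trimws(at$elety),
    resno      = as.integer(at$resno),
    resname    = trimws(at$resid),
    chain      = chain,
    element    = element,
    is_heavy   = !(element %in% c("H", "D")),
    stringsAsFactors = FALSE
  )
  key <- paste(topo$chain, topo$resno, topo$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("format error: duplicate atom key (chain ", topo$chain[d],
         ", residue ", topo$resno[d], ", atom ", topo$atom_name[d], ")")
  }
  class(topo) <- c("topology", "data.frame")
  topo
}

#' Construct a topology from atom annotations
#'
#' Programmatic constructor used by the synthetic-data generators and tests.
#'
#' @param atom_name,resno,resname,chain,element Per-atom vectors, recycled to
#'   a common length.
#' @return A `topology` object.
#' @export
topology <- function(atom_name, resno, resname = "ALA", chain = "A",
                     element = "C") {
  n <- max(length(atom_name), length(resno))
  topo <- data.frame(
    atom_index = seq_len(n) - 1L,
    atom_name  = rep_len(atom_name, n),
    resno      = as.integer(rep_len(resno, n)),
    resname    = rep_len(resname, n),
    chain      = rep_len(chain, n),
    element    = toupper(rep_len(element, n)),
    stringsAsFactors = FALSE
  )
  topo$is_heavy <- !(topo$element %in% c("H", "D"))
  key <- paste(topo$chain, topo$resno, topo$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) key in topology")
  }
  class(topo) <- c("topology", "data.frame")
  topo
}

#' Bundle coordinates and times into a frame set
#'
#' @param xyz Either a T x 3N matrix (x1,y1,z1,x2,...) or a T x N x 3 array
#'   of coordinates in Angstrom.
#' @param times Frame times in ns, strictly increasing. Defaults to
#'   0, 1, 2, ... ns.
#' @param topology The matching `topology` (N atoms).
#' @return A `frameset` object with elements `xyz` (T x 3N matrix), `times`
#'   and `topology`.
#' @export
frameset <- function(xyz, times = NULL, topology) {
  if (length(dim(xyz)) == 3L) {
    d <- dim(xyz)
    m <- matrix(0, d[1L], d[2L] * 3L)
    for (k in 1:3) m[, seq.int(k, by = 3L, length.out = d[2L])] <- xyz[, , k]
    xyz <- m
  }
  fs_build(xyz, times, topology)
}

# Internal constructor on the T x 3N matrix layout (bio3d xyz convention).
fs_build <- function(xyz, times, topology) {
  xyz <- as.matrix(xyz)
  n_atoms <- nrow(topology)
  if (ncol(xyz) != 3L * n_atoms) {
    stop("shape error: coordinate matrix has ", ncol(xyz) / 3,
         " atoms, topology has ", n_atoms)
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame set")
  T_ <- nrow(xyz)
  if (T_ < 1L) stop("frame set must contain at least one frame")
  if (is.null(times)) times <- as.numeric(seq_len(T_) - 1L)
  if (length(times) != T_) stop("times length does not match frame count")
  if (T_ > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(xyz = xyz, times = as.numeric(times), topology = topology),
            class = "frameset")
}

#' Number of frames / atoms in a frame set
#' @param fs A `frameset`.
#' @return Integer count.
#' @export
n_frames <- function(fs) nrow(fs$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(fs) ncol(fs$xyz) %/% 3L

#' Extract one frame as an N x 3 coordinate matrix
#' @param fs A `frameset`.
#' @param i Frame index (1-based).
#' @return N x 3 matrix in Angstrom.
#' @export
frame_coords <- function(fs, i = 1L) {
  matrix(fs$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' @export
print.frameset <- function(x, ...) {
  cat("frameset:", n_frames(x), "frames x", n_atoms(x), "atoms;",
      "t =", x$times[1L], "..", x$times[n_frames(x)], "ns\n")
  invisible(x)
}

#' Read trajectory frames
#'
#' Reads one or more trajectory files (multi-model PDB, or the packed binary
#' container written by [write_frames_bin()]) and concatenates them in
#' argument order. Binary files carry their own frame times; PDB models are
#' assigned times continuing at 1 ns spacing from the previous frame.
#'
#' @param paths Character vector of trajectory file paths.
#' @param topology The `topology` the frames must match (atom count/order).
#' @return A `frameset`.
#' @export
read_frames <- function(paths, topology) {
  stopifnot(length(paths) >= 1L)
  xyz_list <- list()
  times_list <- list()
  t_last <- -1
  for (p in paths) {
    piece <- if (is_frames_bin(p)) read_frames_bin_raw(p) else
      read_frames_pdb_raw(p)
    n_at <- ncol(piece$xyz) %/% 3L
    if (n_at != nrow(topology)) {
      stop("shape error in '", p, "' at frame ",
           length(unlist(times_list)) + 1L, ": ", n_at,
           " atoms, expected ", nrow(topology))
    }
    tm <- piece$times
    if (is.null(tm)) tm <- as.numeric(seq_len(nrow(piece$xyz)) - 1L)
    # keep concatenated times strictly increasing across files
    if (length(tm) && tm[1L] <= t_last) tm <- tm + (t_last + 1 - tm[1L])
    t_last <- tm[length(tm)]
    xyz_list[[length(xyz_list) + 1L]] <- piece$xyz
    times_list[[length(times_list) + 1L]] <- tm
  }
  fs_build(do.call(rbind, xyz_list), unlist(times_list), topology)
}

is_frames_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  identical(readBin(con, "raw", 4L), .frames_magic)
}

read_frames_pdb_raw <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- unclass(xyz)
  keep <- altloc_keep(pdb$atom)
  if (!all(keep)) xyz <- xyz[, atom_cols(which(keep) - 1L), drop = FALSE]
  list(xyz = xyz, times = NULL)
}

read_frames_bin_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .frames_magic)) {
    stop("format error: '", path, "' is not a packed frame container")
  }
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  n_at <- hdr[1L]; T_ <- hdr[2L]
  coords <- readBin(con, "numeric", T_ * n_at * 3L, size = 4L,
                    endian = "little")
  times <- readBin(con, "numeric", T_, size = 8L, endian = "little")
  if (length(coords) != T_ * n_at * 3L || length(times) != T_) {
    stop("format error: truncated frame container '", path, "'")
  }
  list(xyz = matrix(coords, nrow = T_, byrow = TRUE), times = times)
}

#' Write frames as a multi-model PDB
#'
#' Coordinates are written at the PDB's 3-decimal precision; times are not
#' representable in the PDB format and are dropped (readers re-assign
#' 0, 1, 2, ... ns).
#'
#' @param fs A `frameset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(fs, path) {
  topo <- fs$topology
  bio3d::write.pdb(file = path, xyz = fs$xyz,
                   resno = topo$resno, resid = topo$resname,
                   elety = topo$atom_name, chain = topo$chain,
                   elesy = topo$element)
  invisible(path)
}

#' Write frames in the packed binary container
#'
#' Layout: 4 magic bytes, int32 N, int32 T, then T*N*3 little-endian float32
#' coordinates in Angstrom (frame-major, per atom x,y,z), then T float64
#' times in ns. Compact lossy (float32) storage for large synthetic runs.
#'
#' @inheritParams write_frames_pdb
#' @return `path`, invisibly.
#' @export
write_frames_bin <- function(fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.frames_magic, con)
  writeBin(c(n_atoms(fs), n_frames(fs)), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(fs$xyz)), con, size = 4L, endian = "little")
  writeBin(fs$times, con, size = 8L, endian = "little")
  invisible(path)
}

#' Define a named residue segment
#'
#' Segments are the unit of the coupling analysis, e.g. the mobile pocket lid
#' L663-Q676 or the TRP-like/S6 span V961-V1005.
#'
#' @param name Segment label.
#' @param chain Chain identifier.
#' @param first,last First and last author residue numbers (inclusive).
#' @return A `segment_def` object.
#' @export
segment_def <- function(name, chain, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (first > last) stop("segment '", name, "': first_residue > last_residue")
  structure(list(name = name, chain = chain,
                 first_residue = first, last_residue = last),
            class = "segment_def")
}

#' Select atoms of a residue segment
#'
#' @param topology A `topology`.
#' @param segment A `segment_def`.
#' @param heavy_only Keep only non-hydrogen atoms (the convention used for
#'   all covariance work).
#' @param calpha_only Keep only atoms named CA.
#' @return An `atom_selection`: list with `atom_indices` (0-based, topology
#'   order) and `residue_keys` (data frame of chain/resno per atom).
#' @export
select_atoms <- function(topology, segment, heavy_only = TRUE,
                         calpha_only = FALSE) {
  if (!segment$chain %in% topology$chain) {
    stop("selection error: chain '", segment$chain, "' not in topology")
  }
  keep <- topology$chain == segment$chain &
    topology$resno >= segment$first_residue &
    topology$resno <= segment$last_residue
  if (heavy_only) keep <- keep & topology$is_heavy
  if (calpha_only) keep <- keep & topology$atom_name == "CA"
  idx <- topology$atom_index[keep]
  if (length(idx) == 0L) {
    warning("empty selection for segment '", segment$name, "' (",
            segment$first_residue, "-", segment$last_residue, " chain ",
            segment$chain, ")")
  }
  structure(list(
    atom_indices = idx,
    residue_keys = data.frame(chain = topology$chain[keep],
                              resno = topology$resno[keep],
                              stringsAsFactors = FALSE)
  ), class = "atom_selection")
}

# Internal: 1-based xyz-matrix column indices for a selection.
sel_cols <- function(selection) {
  i <- selection$atom_indices
  as.vector(rbind(3L * i + 1L, 3L * i + 2L, 3L * i + 3L))
}

# Internal: columns for arbitrary 0-based atom indices.
atom_cols <- function(atom_indices) {
  as.vector(rbind(3L * atom_indices + 1L, 3L * atom_indices + 2L,
                  3L * atom_indices + 3L))
}
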