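# Fixtures are built in code; nothing binary ships with the tests.

# One fixed-format PDB ATOM/HETATM line.
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     element = "C", alt = " ", occ = 1, icode = " ",
                     record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, icode,
          x, y, z, occ, 0, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Poly-ALA chain: residues first..last, five heavy atoms (N CA C O CB) and
# one hydrogen each.
poly_ala_topology <- function(first = 663L, last = 676L, chain = "A",
                              with_h = TRUE) {
  n_res <- last - first + 1L
  heavy <- c("N", "CA", "C", "O", "CB")
  names_per_res <- if (with_h) c(heavy, "H") else heavy
  el_per_res <- if (with_h) c("N", "C", "C", "O", "C", "H") else
    c("N", "C", "C", "O", "C")
  topology(atom_name = rep(names_per_res, n_res),
           resno = rep(first:last, each = length(names_per_res)),
           resname = "ALA", chain = chain,
           element = rep(el_per_res, n_res))
}

# Frameset with given per-frame N x 3 coordinate list.
frames_from_coords <- function(coord_list, topo, times = NULL) {
  xyz <- do.call(rbind, lapply(coord_list, function(m) as.vector(t(m))))
  frameset(xyz, times, topo)
}

# Small topology of `n_res` residues x `atoms_per_res` carbon atoms.
grid_topology <- function(n_res, atoms_per_res = 3L, chain = "A",
                          first = 1L) {
  topology(atom_name = rep(paste0("C", seq_len(atoms_per_res)), n_res),
           resno = rep(seq.int(first, length.out = n_res),
                       each = atoms_per_res),
           resname = "GLY", chain = chain, element = "C")
}

# Exhaustive (x, y) grid oracle for one pore slice: the optimizer must match
# this within its search tolerance.
grid_slice_radius <- function(coords, radii, z, xy_half = 3, res = 0.05) {
  g <- seq(-xy_half, xy_half, by = res)
  best <- -Inf
  for (x in g) {
    dx2 <- (coords[, 1L] - x)^2
    for (y in g) {
      cl <- min(sqrt(dx2 + (coords[, 2L] - y)^2 + (coords[, 3L] - z)^2) -
                  radii)
      if (cl > best) best <- cl
    }
  }
  max(best, 0)
}

# Hand-built MI matrix for aggregation arithmetic tests.
mi_df <- function(resnoA, resnoB, mi, segA = "segA", segB = "segB",
                  chainA = "A", chainB = "A", run = NA_character_,
                  monomer = NA_character_) {
  out <- data.frame(
    chainA = chainA, resnoA = as.integer(resnoA), resnameA = "GLY",
    segmentA = segA, chainB = chainB, resnoB = as.integer(resnoB),
    resnameB = "GLY", segmentB = segB, mi_nats = mi,
    floor_applied = FALSE, src_run = run, src_monomer = monomer,
    stringsAsFactors = FALSE)
  class(out) <- c("mi_matrix", "data.frame")
  out
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
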