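# End-to-end analysis pipelines tying the stages into the three analyses
# (coupling pathways, pocket occupancy, pore profile), with TSV outputs and
# a machine-readable manifest per run. A thin command-line wrapper over
# these functions ships in inst/cli/channelmi.R.

# Internal: JSON manifest next to a command's outputs. Deterministic
# content (no timestamps) so reruns with identical inputs are
# byte-identical.
write_manifest <- function(output_dir, command, config, outputs) {
  man <- list(
    command = command,
    package = "channelmi",
    version = as.character(utils::packageVersion("channelmi")),
    config = config,
    config_hash = unname(md5_of(config)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(output_dir, outputs))), outputs))
  )
  jsonlite::write_json(man, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

md5_of <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  tools::md5sum(tf)
}

#' Read a run configuration
#'
#' Loads a YAML configuration for the command-line pipelines. The config is
#' echoed verbatim into every output manifest so a run is reproducible from
#' its outputs.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Internal: resolve per-chain segment_def list from config-style segments
# (list of list(name, first, last)) for a chain.
segments_for_chain <- function(segments, chain) {
  lapply(segments, function(s) {
    segment_def(s$name, chain, s$first, s$last)
  })
}

#' Mutual-information pathway analysis pipeline
#'
#' For every run and monomer: superpose the trajectory on the fit segment's
#' Calpha atoms (per-monomer alignment), compute the residue-pair MI matrix
#' over the analysis segments, then pool all (run, monomer) matrices by
#' entrywise maximum, summarise every segment pair by its mean residue-pair
#' maximum, and extract the strongest pairs as a pathway edge list.
#'
#' @param frames_by_run Named list of `frameset`s, one per repeat run.
#' @param segments List of segment descriptors `list(name, first, last)`
#'   (chains are supplied per monomer).
#' @param monomers Chain labels of the monomers to analyse.
#' @param fit_segment Name of the segment whose Calpha atoms define the
#'   per-monomer fit (default `"TRPL"`).
#' @param eigenvalue_floor Eigenvalue floor in Angstrom^2.
#' @param top_k,min_value Edge-list size and MI threshold (nats).
#' @param output_dir Optional directory for TSV outputs + manifest.
#' @return List with `max_matrix`, `per_unit` (all per-(run, monomer)
#'   matrices), `segment_means` (data frame), `top` (edge list).
#' @export
run_mi_analysis <- function(frames_by_run, segments, monomers,
                            fit_segment = "TRPL", eigenvalue_floor = 1e-8,
                            top_k = 25L, min_value = 0, output_dir = NULL) {
  stopifnot(length(frames_by_run) >= 1L)
  if (is.null(names(frames_by_run))) {
    names(frames_by_run) <- paste0("run", seq_along(frames_by_run))
  }
  per_unit <- list()
  for (run in names(frames_by_run)) {
    fs <- frames_by_run[[run]]
    for (ch in monomers) {
      segs <- segments_for_chain(segments, ch)
      fit <- segs[[which(vapply(segs, `[[`, "", "name") == fit_segment)]]
      fit_sel <- select_atoms(fs$topology, fit, calpha_only = TRUE)
      aligned <- align_frameset(fs, fit_sel)
      per_unit[[paste(run, ch, sep = ":")]] <-
        mi_matrix(aligned, segs, eigenvalue_floor = eigenvalue_floor,
                  run_id = run, monomer_id = ch)
    }
  }
  max_m <- aggregate_max(per_unit)
  seg_names <- vapply(segments, `[[`, "", "name")
  pairs <- utils::combn(seg_names, 2L)
  segment_means <- data.frame(
    segmentA = pairs[1L, ], segmentB = pairs[2L, ],
    mean_residue_pair_max = apply(pairs, 2L, function(p) {
      segment_pair_mean(max_m, p[1L], p[2L])$mean_of_maxima
    })
  )
  top <- top_pairs(max_m, top_k, min_value)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_mi_tsv(max_m, file.path(output_dir, "mi_max.tsv"))
    utils::write.table(segment_means,
                       file.path(output_dir, "segment_pair_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_mi_tsv(top, file.path(output_dir, "top_pairs.tsv"))
    write_manifest(output_dir, "mi",
                   list(runs = names(frames_by_run), monomers = monomers,
                        segments = segments, fit_segment = fit_segment,
                        eigenvalue_floor = eigenvalue_floor,
                        top_k = top_k, min_value = min_value),
                   c("mi_max.tsv", "segment_pair_means.tsv",
                     "top_pairs.tsv"))
  }
  list(max_matrix = max_m, per_unit = per_unit,
       segment_means = segment_means, top = top)
}

#' Pocket open/closed occupancy pipeline
#'
#' Computes the lid width series for every monomer of every run, classifies
#' frames at the cutoff, and pools closed-state occupancy over all
#' (run, monomer) units.
#'
#' @param frames_by_run Named list of `frameset`s.
#' @param monomers Chain labels.
#' @param residue_pair Lid residue numbers (default `c(610, 667)`).
#' @param cutoff Closed/open cutoff in Angstrom (default 11).
#' @param window Moving-average window in ns for the smoothed plotting
#'   series (default 2; occupancies always use the raw series).
#' @param scenario Label for the summary row.
#' @param output_dir Optional output directory.
#' @return List with `summary` (an `occupancy_summary`), `series` (list of
#'   `pocket_series`), `states` (list of `state_series`).
#' @export
run_pocket_analysis <- function(frames_by_run, monomers,
                                residue_pair = c(610L, 667L), cutoff = 11,
                                window = 2, scenario = "",
                                output_dir = NULL) {
  if (is.null(names(frames_by_run))) {
    names(frames_by_run) <- paste0("run", seq_along(frames_by_run))
  }
  series <- list(); states <- list(); run_ids <- character(0)
  for (run in names(frames_by_run)) {
    for (ch in monomers) {
      key <- paste(run, ch, sep = ":")
      s <- pocket_width_series(frames_by_run[[run]], ch, residue_pair)
      series[[key]] <- s
      states[[key]] <- classify_states(s, cutoff)
      run_ids <- c(run_ids, run)
    }
  }
  summ <- occupancy(states, scenario = scenario, run_ids = run_ids)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (key in names(series)) {
      f <- paste0("pocket_", gsub(":", "_", key), ".tsv")
      write_pocket_tsv(series[[key]], file.path(output_dir, f), cutoff)
      sm <- moving_average(series[[key]], window)
      fsm <- paste0("pocket_", gsub(":", "_", key), "_smoothed.tsv")
      utils::write.table(
        data.frame(time_ns = sm$times, width_A = sm$widths),
        file.path(output_dir, fsm), sep = "\t", quote = FALSE,
        row.names = FALSE)
      files <- c(files, f, fsm)
    }
    sum_df <- data.frame(scenario = summ$scenario,
                         population_closed_pct = summ$fraction_closed,
                         dispersion_pct = summ$dispersion,
                         n_units = summ$n_units,
                         total_time_us = summ$total_time)
    utils::write.table(sum_df, file.path(output_dir, "occupancy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "occupancy.tsv")
    write_manifest(output_dir, "pocket",
                   list(runs = names(frames_by_run), monomers = monomers,
                        residue_pair = residue_pair, cutoff = cutoff,
                        window = window, scenario = scenario), files)
  }
  list(summary = summ, series = series, states = states)
}

#' Pore radius profile pipeline
#'
#' Profiles every frame (optionally strided) on a common z grid, averages
#' the profiles with per-slice spread, and extracts the minimum-radius time
#' series.
#'
#' @param frames A `frameset` (tetramer-wide alignment is the caller's
#'   responsibility; profiles of rigidly moving frames differ unless
#'   pre-aligned).
#' @param pore_selection `atom_selection` of pore-lining atoms.
#' @param axis,z_range,z_step,vdw,max_probe See [pore_radius_profile()];
#'   `axis` and `z_range` default to the first frame's principal axis and
#'   extent so all frames share one grid.
#' @param stride Profile every `stride`-th frame.
#' @param output_dir Optional output directory.
#' @return List with `average` (a `pore_profile`), `minima` (data frame),
#'   `profiles` (per-frame list).
#' @export
run_pore_analysis <- function(frames, pore_selection, axis = NULL,
                              z_range = NULL, z_step = 0.5,
                              vdw = vdw_radii(), max_probe = 10,
                              stride = 1L, output_dir = NULL) {
  coords1 <- frame_coords(frames, 1L)[pore_selection$atom_indices + 1L, ,
                                      drop = FALSE]
  if (is.null(axis)) axis <- principal_axis(coords1)
  if (is.null(z_range)) z_range <- range(coords1 %*% axis)
  idx <- seq.int(1L, n_frames(frames), by = stride)
  profiles <- lapply(idx, function(t) {
    pore_radius_profile(frames, pore_selection, frame = t, axis = axis,
                        z_range = z_range, z_step = z_step, vdw = vdw,
                        max_probe = max_probe)
  })
  avg <- average_profile(profiles)
  minima <- data.frame(
    time_ns = frames$times[idx],
    min_radius_A = vapply(profiles, `[[`, 0, "min_radius"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile_tsv(avg, file.path(output_dir, "pore_profile.tsv"))
    utils::write.table(minima, file.path(output_dir, "pore_minima.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(output_dir, "pore",
                   list(axis = as.numeric(axis),
                        z_range = as.numeric(z_range), z_step = z_step,
                        max_probe = max_probe, stride = stride),
                   c("pore_profile.tsv", "pore_minima.tsv"))
  }
  list(average = avg, minima = minima, profiles = profiles)
}

#' Generate a synthetic fixture with its ground-truth sidecar
#'
#' Dispatches to the synthetic-data generators, writes the fixture as a
#' multi-model PDB (plus packed binary frames), and a `truth.json` sidecar
#' holding the generator's closed-form ground truth for downstream
#' assertions.
#'
#' @param kind One of `"trpa1"`, `"coupled_pair"`, `"markov_pocket"`,
#'   `"toy_pore"`.
#' @param output_dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to the generator.
#' @return The generator's return value, invisibly.
#' @export
run_simulate <- function(kind = c("trpa1", "coupled_pair", "markov_pocket",
                                  "toy_pore"),
                         output_dir, seed = 1L, ...) {
  kind <- match.arg(kind)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  args <- list(...)
  truth <- list(kind = kind, seed = seed)
  files <- character(0)
  res <- switch(kind,
    trpa1 = {
      g <- gen_trpa1_like(seed = seed, ...)
      write_frames_pdb(g$frames, file.path(output_dir, "trajectory.pdb"))
      write_frames_bin(g$frames, file.path(output_dir, "trajectory.cmi"))
      truth$analytic_mi <- g$analytic_mi
      truth$coupled_pair <- g$coupled_pair
      files <- c("trajectory.pdb", "trajectory.cmi")
      g
    },
    coupled_pair = {
      g <- do.call(gen_coupled_pair, c(args, list(seed = seed)))
      write_frames_pdb(g$frames, file.path(output_dir, "trajectory.pdb"))
      truth$analytic_mi <- g$analytic_mi
      files <- "trajectory.pdb"
      g
    },
    markov_pocket = {
      g <- do.call(gen_markov_pocket, c(args, list(seed = seed)))
      utils::write.table(
        data.frame(time_ns = g$series$times, width_A = g$series$widths),
        file.path(output_dir, "pocket_widths.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      truth$true_closed_fraction <- g$true_closed_fraction
      files <- "pocket_widths.tsv"
      g
    },
    toy_pore = {
      g <- do.call(gen_toy_pore, args)
      write_frames_pdb(g$frames, file.path(output_dir, "pore.pdb"))
      truth$true_profile <- g$true_profile
      files <- "pore.pdb"
      g
    })
  jsonlite::write_json(truth, file.path(output_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "truth.json")
  write_manifest(output_dir, paste0("simulate-", kind),
                 c(list(seed = seed), args), files)
  invisible(res)
}
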