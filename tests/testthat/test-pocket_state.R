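test_that("pocket width is the lid Calpha-Calpha distance", {
  topo <- topology(atom_name = c("CA", "CA"), resno = c(610L, 667L),
                   resname = c("LYS", "LEU"), chain = "A", element = "C")
  fs <- frames_from_coords(list(
    rbind(c(0, 0, 0), c(15.5, 0, 0)),   # pocket-open reference width
    rbind(c(0, 0, 0), c(9.4, 0, 0)),    # pocket-closed reference width
    rbind(c(1, 1, 1), c(1, 1, 1))
  ), topo)
  s <- pocket_width_series(fs, "A")
  expect_equal(s$widths, c(15.5, 9.4, 0))
  # rigid invariance: distances unchanged under any rigid transform
  set.seed(2)
  R <- random_rotation_matrix()
  fs2 <- fs
  fs2$xyz <- t(apply(fs$xyz, 1, function(v) {
    as.vector(t(sweep(matrix(v, ncol = 3, byrow = TRUE) %*% t(R), 2,
                      c(3, 1, -2), "+")))
  }))
  expect_equal(pocket_width_series(fs2, "A")$widths, s$widths,
               tolerance = 1e-10)
  # missing residue names the lookup
  expect_error(pocket_width_series(fs, "B"), "chain B")
})

test_that("moving averages are centered, truncated and bounded", {
  mk <- function(w, t = seq_along(w) - 1) {
    structure(list(monomer_id = "A", times = t, widths = w,
                   residue_pair = c(610L, 667L)), class = "pocket_series")
  }
  # constant series unchanged
  cs <- moving_average(mk(rep(12, 50)), window = 2)
  expect_equal(cs$widths, rep(12, 50))
  # window below the frame spacing is the identity
  s <- mk(c(10, 16, 10, 16), t = c(0, 10, 20, 30))
  expect_equal(moving_average(s, window = 1)$widths, s$widths)
  # step series: smoothed values bracketed by the step levels
  step <- mk(c(rep(10, 30), rep(16, 30)))
  sm <- moving_average(step, window = 8)
  expect_true(all(sm$widths >= 10 & sm$widths <= 16))
  expect_equal(sm$times, step$times)
  # forced arithmetic: centered window of +/-1 frame at 1 ns spacing
  tri <- moving_average(mk(c(0, 3, 6, 9)), window = 2)
  expect_equal(tri$widths, c(1.5, 3, 6, 7.5))
})

test_that("state classification uses a strict cutoff (boundary is open)", {
  mk <- function(w) structure(list(monomer_id = "A",
                                   times = seq_along(w) - 1, widths = w,
                                   residue_pair = c(610L, 667L)),
                              class = "pocket_series")
  st <- classify_states(mk(c(9.4, 15.5, 11.0, 10.999)))
  expect_equal(st$closed, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(st$cutoff, 11)
})

test_that("occupancy pools time-weighted closed fractions across units", {
  mk_state <- function(closed, t = seq_along(closed) - 1) {
    structure(list(times = t, closed = closed, cutoff = 11,
                   monomer_id = "A"), class = "state_series")
  }
  # equal spacing, half closed
  s <- occupancy(list(mk_state(c(TRUE, TRUE, FALSE, FALSE))))
  expect_equal(s$fraction_closed, 50)
  # all-open: 0 % with zero dispersion
  s0 <- occupancy(list(mk_state(rep(FALSE, 10)), mk_state(rep(FALSE, 10))))
  expect_equal(s0$fraction_closed, 0)
  expect_equal(s0$dispersion, 0)
  # complement identity and ordering invariance
  set.seed(12)
  units <- lapply(1:6, function(i) mk_state(runif(100) < 0.3))
  a <- occupancy(units)
  b <- occupancy(rev(units))
  expect_equal(a$fraction_closed, b$fraction_closed)
  expect_equal(a$fraction_closed + (100 - a$fraction_closed), 100)
  expect_equal(a$n_units, 6L)
  expect_error(occupancy(list()), "empty")
})

test_that("Markov pocket units recover the stationary closed fraction", {
  # 12 units of 1 us at dt = 0.1 ns; stationary closed fraction 0.25
  k_oc <- 0.01; k_co <- 0.03
  units <- lapply(1:12, function(i) {
    gen_markov_pocket(k_oc, k_co, duration = 1000, dt = 0.1,
                      seed = 100 + i)
  })
  expect_equal(units[[1]]$true_closed_fraction, 0.25)
  states <- lapply(units, function(u) classify_states(u$series))
  summ <- occupancy(states)
  expect_equal(summ$n_units, 12L)
  expect_equal(summ$total_time, 12, tolerance = 0.01)  # 12 us pooled
  # analytic standard error of the pooled time-average occupancy of a
  # two-state Markov chain: var = 2 pi_o pi_c tau / D_total
  tau <- 1 / (k_oc + k_co)
  se <- sqrt(2 * 0.25 * 0.75 * tau / 12000) * 100
  expect_lt(abs(summ$fraction_closed - 25), 3 * se)
  # per-unit dispersion is reported as a spread, not an SE
  expect_gt(summ$dispersion, 0)
})

test_that("out-of-pocket occupancy tracks the contact criterion", {
  topo <- topology(atom_name = c("C1", "C1"), resno = c(1L, 2L),
                   resname = c("LIG", "POC"), chain = "A", element = "C")
  lig <- select_atoms(topo, segment_def("lig", "A", 1, 1))
  poc <- select_atoms(topo, segment_def("poc", "A", 2, 2))
  far <- frames_from_coords(rep(list(rbind(c(0, 0, 0), c(20, 0, 0))), 5),
                            topo)
  expect_equal(out_of_pocket_occupancy(far, lig, poc), 100)
  near <- frames_from_coords(rep(list(rbind(c(0, 0, 0), c(2, 0, 0))), 5),
                             topo)
  expect_equal(out_of_pocket_occupancy(near, lig, poc), 0)
  # switching with a known dwell fraction: one interior frame out of a
  # 3 ns span carries 1 ns of midpoint-interval weight
  sw <- frames_from_coords(list(
    rbind(c(0, 0, 0), c(2, 0, 0)), rbind(c(0, 0, 0), c(2, 0, 0)),
    rbind(c(0, 0, 0), c(20, 0, 0)), rbind(c(0, 0, 0), c(2, 0, 0))
  ), topo)
  expect_equal(out_of_pocket_occupancy(sw, lig, poc), 100 / 3,
               tolerance = 1e-9)
})

test_that("single-structure width check works on the synthetic stand-in", {
  p_open <- tempfile(fileext = ".pdb")
  write_synthetic_pocket_structure(p_open, width = 15.5)
  expect_equal(pocket_width_structure(p_open), 15.5, tolerance = 0.01)
  p_closed <- tempfile(fileext = ".pdb")
  write_synthetic_pocket_structure(p_closed, width = 9.4)
  w <- pocket_width_structure(p_closed)
  expect_equal(w, 9.4, tolerance = 0.01)
  expect_true(w < 11)   # classifies closed at the standard cutoff
})
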