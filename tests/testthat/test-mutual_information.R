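test_that("trajectory covariance matches forced arithmetic and samples", {
  topo <- grid_topology(1, 1)
  sel <- select_atoms(topo, segment_def("r", "A", 1, 1))
  # one atom, x in {0, 2}, y = z = 0: population var(x) = 1
  fs <- frameset(rbind(c(0, 0, 0), c(2, 0, 0)), topology = topo)
  cv <- traj_covariance(fs, sel)
  expect_equal(cv$matrix,
               diag(c(1, 0, 0)), tolerance = 1e-12, ignore_attr = TRUE)
  # identical frames -> zero matrix
  fs0 <- frameset(rbind(c(1, 2, 3), c(1, 2, 3)), topology = topo)
  expect_equal(max(abs(traj_covariance(fs0, sel)$matrix)), 0)
  # T-1 denominator doubles the two-frame variance
  expect_equal(traj_covariance(fs, sel, denominator = "T-1")$matrix[1, 1], 2)
  expect_error(traj_covariance(frameset(matrix(0, 1, 3), topology = topo),
                               sel), "insufficient")
  # sampling oracle: 20,000 draws from a known 6x6 covariance
  topo2 <- grid_topology(1, 2)
  sel2 <- select_atoms(topo2, segment_def("r", "A", 1, 1))
  C <- matrix(0.9, 6, 6) + 0.1 * diag(6)  # dense, every entry well away
  fs2 <- gen_gaussian_trajectory(topo2, matrix(0, 2, 3), C,  # from zero
                                 n_frames = 20000, seed = 8)
  Chat <- traj_covariance(fs2, sel2)$matrix
  expect_lt(max(abs(Chat - C) / abs(C)), 0.05)
})

test_that("configurational entropy reproduces Gaussian closed forms", {
  half_ln_2pie <- 0.5 * log(2 * pi * exp(1))
  e1 <- config_entropy(matrix(1))
  expect_equal(e1$value, half_ln_2pie, tolerance = 1e-9)
  expect_false(e1$floor_applied)
  # d-dimensional identity
  for (d in c(3L, 9L)) {
    expect_equal(config_entropy(diag(d))$value, d * half_ln_2pie,
                 tolerance = 1e-9)
  }
  # 1-D variance 4: + ln 2
  expect_equal(config_entropy(matrix(4))$value, half_ln_2pie + log(2),
               tolerance = 1e-9)
  # singular direction triggers the floor
  es <- config_entropy(diag(c(1, 0)), eigenvalue_floor = 1e-8)
  expect_true(es$floor_applied)
  expect_equal(es$value, half_ln_2pie + 0.5 * log(2 * pi * exp(1) * 1e-8),
               tolerance = 1e-9)
  expect_error(config_entropy(diag(c(1, -1))), "invalid covariance")
})

test_that("pairwise MI approaches the Gaussian closed form", {
  g <- gen_coupled_pair(rho = 0.9, d_per_block = 1, n_frames = 50000,
                        seed = 7)
  mi <- pairwise_mi(g$frames, g$selection_a, g$selection_b)
  expect_equal(g$analytic_mi, -0.5 * log(1 - 0.81), tolerance = 1e-12)
  expect_lt(abs(as.numeric(mi) - g$analytic_mi), 0.02)
  # 3-D blocks
  g3 <- gen_coupled_pair(rho = 0.5, d_per_block = 3, n_frames = 50000,
                         seed = 12)
  mi3 <- pairwise_mi(g3$frames, g3$selection_a, g3$selection_b)
  expect_lt(abs(as.numeric(mi3) - g3$analytic_mi), 0.02)
})

test_that("MI is symmetric, non-negative and invariant to reparametrization", {
  g <- gen_coupled_pair(rho = 0.6, d_per_block = 3, n_frames = 3000,
                        seed = 4)
  fs <- g$frames
  a <- g$selection_a; b <- g$selection_b
  mi_ab <- pairwise_mi(fs, a, b)
  mi_ba <- pairwise_mi(fs, b, a)
  expect_identical(as.numeric(mi_ab), as.numeric(mi_ba))
  expect_gte(as.numeric(mi_ab), 0)
  # uniform coordinate scaling cancels in the determinant ratio
  for (s in c(0.1, 7)) {
    sc <- fs; sc$xyz <- fs$xyz * s
    expect_lt(abs(as.numeric(pairwise_mi(sc, a, b)) -
                    as.numeric(mi_ab)), 1e-8)
  }
  # independent invertible linear maps on each block
  set.seed(3)
  d <- 3L * length(a$atom_indices)
  Ma <- diag(d) + matrix(rnorm(d * d, sd = 0.2), d)
  Mb <- diag(d) + matrix(rnorm(d * d, sd = 0.2), d)
  lin <- fs
  ca <- channelmi:::sel_cols(a); cb <- channelmi:::sel_cols(b)
  lin$xyz[, ca] <- fs$xyz[, ca] %*% t(Ma)
  lin$xyz[, cb] <- fs$xyz[, cb] %*% t(Mb)
  expect_lt(abs(as.numeric(pairwise_mi(lin, a, b)) - as.numeric(mi_ab)),
            1e-6)
})

test_that("independent blocks score near-zero MI, below the shuffled null", {
  g <- gen_coupled_pair(rho = 0, d_per_block = 9, n_frames = 50000,
                        seed = 19)
  mi <- pairwise_mi(g$frames, g$selection_a, g$selection_b)
  expect_lt(as.numeric(mi), 0.05)
  null <- mi_shuffle_null(g$frames, g$selection_a, g$selection_b,
                          n_perm = 100, seed = 23)
  expect_length(null, 100L)
  expect_lte(as.numeric(mi), quantile(null, 0.99) + 1e-12)
})

test_that("overlapping selections and singular joints are handled", {
  topo <- grid_topology(2, 1)
  seg <- segment_def("r1", "A", 1, 1)
  sel1 <- select_atoms(topo, seg)
  expect_error(pairwise_mi(gen_trpa1_like(n_frames = 5, seed = 1)$frames,
                           sel1, sel1), "selection error")
  # atom 2 is an exact copy of atom 1 offset by 1 A: joint covariance is
  # singular, MI is large, finite and flagged
  set.seed(9)
  base <- matrix(rnorm(60), 20)
  xyz <- cbind(base, base + 1)
  fs <- frameset(xyz, topology = topo)
  sel2 <- select_atoms(topo, segment_def("r2", "A", 2, 2))
  mi <- pairwise_mi(fs, sel1, sel2)
  expect_true(is.finite(as.numeric(mi)))
  expect_gt(as.numeric(mi), 5)
  expect_true(attr(mi, "floor_applied"))
  # a larger floor shrinks the singular-direction contribution
  mi_hi <- pairwise_mi(fs, sel1, sel2, eigenvalue_floor = 1e-4)
  expect_lt(as.numeric(mi_hi), as.numeric(mi))
})

test_that("mi_matrix finds the planted coupled pair among residues", {
  g <- gen_trpa1_like(n_frames = 400, seed = 6)
  segs <- g$segments$A
  fit <- select_atoms(g$topology, segs$TRPL, calpha_only = TRUE)
  al <- align_frameset(g$frames, fit)
  m <- mi_matrix(al, segs, run_id = "run1", monomer_id = "A")
  # two segments of 2 residues -> 4 pairs sanity (combinatorics)
  m2 <- mi_matrix(al, list(segment_def("s1", "A", 663, 664),
                           segment_def("s2", "A", 706, 707)))
  expect_equal(nrow(m2), 4L)
  # planted pair attains the matrix maximum
  top <- m[which.max(m$mi_nats), ]
  expect_equal(c(top$resnoA, top$resnoB), g$coupled_pair)
  expect_equal(top$src_run, "run1")
  # all-independent fixture: maximum below the shuffled-null tail
  g0 <- gen_trpa1_like(n_frames = 400, seed = 61, coupling = 0)
  al0 <- align_frameset(g0$frames, select_atoms(g0$topology, segs$TRPL,
                                                calpha_only = TRUE))
  m0 <- mi_matrix(al0, list(segs$lid, segs$TRPL))
  sel_a <- select_atoms(g0$topology, segment_def("r", "A", 671, 671))
  sel_b <- select_atoms(g0$topology, segment_def("r", "A", 988, 988))
  null <- mi_shuffle_null(al0, sel_a, sel_b, n_perm = 100, seed = 3)
  # null quantile for one pair, corrected for the max over pairs by the
  # permutation spread: the observed max must sit in the null's range
  expect_lt(max(m0$mi_nats), quantile(null, 0.99) + 3 * sd(null))
})

test_that("aggregate_max pools entrywise maxima with provenance", {
  m1 <- mi_df(c(671, 671), c(988, 1001), c(3.0, 1.0), run = "run1",
              monomer = "A")
  m2 <- mi_df(c(671, 671), c(988, 1001), c(5.0, 0.5), run = "run2",
              monomer = "B")
  m3 <- mi_df(c(671, 671), c(988, 1001), c(4.0, 2.0), run = "run3",
              monomer = "C")
  agg <- aggregate_max(list(m1, m2, m3))
  expect_equal(agg$mi_nats, c(5.0, 2.0))
  expect_equal(agg$src_run, c("run2", "run3"))
  expect_equal(agg$src_monomer, c("B", "C"))
  # single matrix -> identity
  one <- aggregate_max(list(m1))
  expect_equal(one$mi_nats, m1$mi_nats)
  # permutation invariance of the values
  agg2 <- aggregate_max(list(m3, m1, m2))
  expect_equal(agg2$mi_nats, agg$mi_nats)
  # every aggregated entry dominates every input entry
  for (m in list(m1, m2, m3)) expect_true(all(agg$mi_nats >= m$mi_nats))
  # mismatched indices are rejected
  bad <- mi_df(671, 999, 1.0)
  expect_error(aggregate_max(list(m1, bad)), "aggregation error")
})

test_that("segment_pair_mean averages per-residue maxima", {
  # 2x2 worked example [[1,2],[3,4]]: per-residue maxima {2,4,3,4} -> 3.25
  m <- mi_df(resnoA = c(1, 1, 2, 2), resnoB = c(11, 12, 11, 12),
             mi = c(1, 2, 3, 4))
  s <- segment_pair_mean(m, "segA", "segB")
  expect_equal(sort(unname(s$per_residue_max)), c(2, 3, 4, 4))
  expect_equal(s$mean_of_maxima, 3.25)
  expect_equal(s$mean_of_maxima, mean(s$per_residue_max), tolerance = 1e-12)
  # constant matrix -> mean c
  mc <- mi_df(resnoA = c(1, 1), resnoB = c(11, 12), mi = c(7, 7))
  expect_equal(segment_pair_mean(mc, "segA", "segB")$mean_of_maxima, 7)
  # a strictly dominated extra pair changes nothing
  m_dom <- rbind(m, mi_df(2, 11, 0.5))
  class(m_dom) <- class(m)
  expect_equal(segment_pair_mean(m_dom, "segA", "segB")$mean_of_maxima,
               3.25)
  # summary lies within the per-residue maxima range
  expect_gte(s$mean_of_maxima, min(s$per_residue_max))
  expect_lte(s$mean_of_maxima, max(s$per_residue_max))
  expect_error(segment_pair_mean(m, "segA", "nope"), "no residue pairs")
})

test_that("top_pairs ranks by value with residue-number tie-breaks", {
  m <- mi_df(resnoA = c(1, 3, 2), resnoB = c(11, 13, 12),
             mi = c(2, 5, 5))
  top <- top_pairs(m, 2)
  expect_equal(top$resnoA, c(2, 3))  # tie at 5 broken by resnoA
  expect_equal(top$mi_nats, c(5, 5))
  expect_equal(nrow(top_pairs(m, 10)), 3L)       # k beyond available
  expect_equal(nrow(top_pairs(m, 5, min_value = 9)), 0L)
})
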