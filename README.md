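# channelmi

Trajectory analysis for ion-channel allostery: Gaussian mutual-information
coupling between residue segments, binding-pocket open/closed occupancy, and
probe-sphere pore-radius profiling.

## The scientific problem

Electrophile-sensing TRP channels such as TRPA1 couple a cytosolic
ligand-binding pocket to the transmembrane pore across ~50 Å of protein.
Molecular-dynamics trajectories of such channels hold the evidence for that
coupling, but extracting it needs three quantitative layers:

1. **Which residues move together?** Under a quasi-harmonic (Gaussian)
   approximation, the configurational entropy of any set of heavy-atom
   coordinates **X** with covariance C(**X**) is

   H(**X**) = ½ ln |2πe C(**X**)|   (nats, coordinates in Å),

   and the mutual information between residues A and B is

   MI(A, B) = H(**X**_A) + H(**X**_B) − H(**X**_{A,B})
            = ½ ln ( |C_A| |C_B| / |C_AB| ).

   Computed for every inter-segment residue pair after superposing frames on
   a stable reference domain (TRP-like domain Cα atoms), pooled by entrywise
   maximum over replicate runs and the four monomers of the homotetramer,
   and summarised per segment pair by the mean of per-residue maxima, this
   yields coupling-pathway edge lists.

2. **Is the pocket open?** Pocket width is the Cα–Cα distance between the
   lower-lid lysine (residue 610) and upper-lid leucine (667); frames with
   width strictly below 11 Å count as closed (the pocket-open and
   pocket-closed reference structures sit at 15.5 Å and 9.4 Å). Closed-state
   occupancy is pooled time-weighted over all (run × monomer) units, with
   the spread across units reported alongside.

3. **Is the pore open?** A probe-sphere profiler slices the structure along
   the channel axis and reports, per slice, the largest sphere radius that
   clears all vdW-inflated atoms, maximized over the slice plane — giving
   radius-vs-axis profiles and minimum-radius time series.

Because published channel studies rarely deposit trajectories, every stage
ships with a seeded synthetic generator whose ground truth is known in
closed form: Gaussian trajectories with prescribed covariance (analytic MI),
two-state Markov-switching pocket widths (analytic occupancy), toy pores of
stacked rings (analytic radius profiles), and rigid-motion frames (exact
superposition residuals). The test suite and acceptance script validate the
full stack against these oracles.

## Worked example

```r
library(channelmi)

# 1. MI estimator vs closed form: two coordinates with correlation 0.9
g  <- gen_coupled_pair(rho = 0.9, d_per_block = 1, n_frames = 50000, seed = 1)
mi <- pairwise_mi(g$frames, g$selection_a, g$selection_b)
sprintf("estimated MI: %.4f nats (analytic %.4f)", mi, g$analytic_mi)
#> "estimated MI: 0.8369 nats (analytic 0.8304)"

# 2. Pathway analysis on a synthetic tetramer with one planted coupled pair
segments <- list(list(name = "lid",  first = 663, last = 676),
                 list(name = "S1",   first = 706, last = 730),
                 list(name = "S4",   first = 842, last = 865),
                 list(name = "TRPL", first = 961, last = 1005))
sim <- gen_trpa1_like(n_frames = 250, seed = 1)
res <- run_mi_analysis(list(run1 = sim$frames), segments,
                       monomers = c("A", "B"))
head(res$top[, c("resnoA", "segmentA", "resnoB", "segmentB", "mi_nats")], 3)
#>   resnoA segmentA resnoB segmentB   mi_nats
#> 1    671      lid    988     TRPL 1.6558302
#> 2    721       S1    851       S4 0.3114067
#> 3    672      lid    961     TRPL 0.3063544

# 3. Pocket occupancy of a Markov-switching width series (truth 25 %)
m   <- gen_markov_pocket(0.01, 0.03, duration = 1000, dt = 0.1, seed = 2)
occupancy(list(classify_states(m$series)), scenario = "synthetic demo")
#> synthetic demo: population closed 23.0 %  (+/- 0.0 over 1 units, 1 us total)
```

The planted pair (671 of the pocket lid with 988 of the TRP-like/S6 span)
heads the edge list at 1.66 nats, an order of magnitude above the
finite-sample background of the unplanted pairs (~0.1–0.3 nats at 250
frames); the MI estimate of the correlated pair sits within sampling error
of −½ ln(1 − ρ²) = 0.8304 nats.

A thin command-line wrapper over the same pipelines (subcommands `simulate`,
`mi`, `pocket`, `pore`, YAML-configured) is installed at
`inst/cli/channelmi.R`.

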