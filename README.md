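# archgait

Forward-dynamic simulation of the stance phase of gait for an articulated
foot model, built to ask a focused surgical question: how much of the
physiological medial/lateral distribution of vertical ground reaction
force (vGRF) does a force-amplifying pulley implant restore in
flexor-digitorum-longus (FDL) to posterior-tibialis (PT) tendon transfer
surgery for adult acquired flatfoot deformity, compared with the direct
transfer?

The simulation methodology is that of robotic cadaver gait rigs: the tibia
is held fixed while a rigid ground plane plays back the inverse motion of
gait beneath the foot over a slowed 4.09 s stance, and nine extrinsic
muscles (PT, FDL, anterior tibialis, toe extensors and flexors, peronei,
soleus) are driven by ten-point piecewise-linear activation profiles.
Four configurations are compared:

| scenario | arch | muscles |
|---|---|---|
| `ARCHED` | neutral | all nine native |
| `FLATFOOT` | first ray dropped 8 mm | PT disabled |
| `FLATFOOT_TT` | dropped | FDL disabled, FDL profile drives the PT path |
| `FLATFOOT_TT_IMPLANT` | dropped | as above, routed through an ideal 2:1 pulley |

The foot is a five-segment chain (talus, lateral hindfoot, medial midfoot,
hallux, lateral toes) with ankle, subtalar, arch and two
metatarsophalangeal joints.  The medial longitudinal arch is a single
revolute joint with a 1 N·m/° torsional spring; five plantar contact
spheres meet the plane through a compliant normal law
`k d^1.5 (1 + c d_dot)` with viscous friction `F_F = F_N f_v v_s`.  The
headline metrics are the double-peak vGRF profile, the peak
medial/lateral split of forefoot loading (first metatarsal + hallux vs
fifth metatarsal + fifth toe), each treatment's lateral shift relative to
the untreated flatfoot, its restoration percentage
`100 (untreated - treated) / (untreated - arched)`, and the
implant-to-transfer improvement ratio.

## Worked example

```r
library(archgait)

cfg <- run_config(scenarios = c("ARCHED", "FLATFOOT", "FLATFOOT_TT",
                                "FLATFOOT_TT_IMPLANT"),
                  out_dir = "archgait_out", seed = 1L)
report <- run_compare(cfg)
print(report)
#> <comparison_report>
#>   peak medial split (%): ARCHED 37.4, FLATFOOT 50.0, FLATFOOT_TT 45.1, FLATFOOT_TT_IMPLANT 39.8
#>   lateral shift: tendon transfer 5.0 pp, implant 10.2 pp
#>   restoration:   tendon transfer 39.1%, implant 80.8%
#>   improvement ratio: 2.1X
```

Reading the output: the arched foot carries 37.4% of peak forefoot vGRF
medially and the untreated flatfoot 50.0% — the collapsed arch shifts
load onto the first ray.  The tendon transfer moves 4.9 percentage points
of that load back laterally and the implant-modified transfer 10.2
points, about 2.1 times the correction, because the pulley delivers twice
the donor tension to the navicular.  `run_compare()` also writes
per-scenario trace CSVs, OpenSim-storage-style `.sto` tables, a summary
CSV, a markdown report and vGRF figures to `out_dir`.

Lower-level entry points: `default_input_bundle()` (synthetic activation
profiles and plane trajectory), `build_foot_model()`,
`calibrate_heel_offset()` (82 kg body-weight scaling),
`simulate_stance()`, `grf_summary()`, `compare_scenarios()`.

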