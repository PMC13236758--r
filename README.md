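# soprec

Quantitative simulation of recognition memory with Wagner's **Standard
Operating Procedures (SOP)** model, for researchers studying spontaneous
object recognition (SOR), relative recency (RR), object-in-place (OIP) and
their multi-sample and Y-maze variants.

Animals explore novel objects more than familiar ones, earlier-sampled
objects more than recent ones, and displaced objects more than objects left
in place.  SOP explains all three preferences with one mechanism —
*priming*.  Each stimulus is a pool of elements in one of three states:
inactive (I), primary activity (A1, which drives exploration), and
refractory secondary activity (A2).  The state proportions follow coupled
ODEs

    dI/dt  = pd2·A2 − (p1 + p2)·I
    dA1/dt = p1·I − pd1·A1
    dA2/dt = pd1·A1 + p2·I − pd2·A2

with `p1` active only while the stimulus is presented.  Elements still in
A2 from a recent encounter cannot re-enter A1 (*self-generated priming*),
and active contexts push an associated object's elements from I straight to
A2 with probability `p2 = min(1, max(0, Σ_c A1_c·(V⁺_c − V⁻_c)))`
(*associatively generated priming*), where each context→object link accrues
excitatory strength `dV⁺/dt = L⁺·A1_ctx·A1_obj` and inhibitory strength
`dV⁻/dt = L⁻·A1_ctx·A2_obj`.  An object's **peak A1 during its test
window** is the behavioural readout, proportional to exploration time.

The package provides:

* the coupled node/link dynamics integrated by fixed-step RK4 (3-s steps,
  compiled core + plain-R reference engine, exact matrix-exponential oracle
  for isolated nodes);
* schedule builders for conceptual task timelines and four published
  procedures, with full counterbalancing enumeration (up to the
  4!·4!·4! = 13,824 context-order permutations of the combined RR+OIP
  battery);
* peak-A1 readouts, contrasts and counterbalance averaging;
* an activation-to-seconds observation model: weighted least squares
  through the origin with two-stage study/task weight equalization, an
  exact study-level bootstrap (all S^S resamples enumerated),
  leave-one-study-out, weighted error metrics, and a synthetic multi-study
  generator with known scaling;
* three sensitivity suites over (pd1, pd2, L⁺, L⁻): parameter space
  partitioning with robust/weak/fail classification, Sobol' variance
  decomposition (Saltelli design with second-order terms, validated against
  closed-form oracles), and a local 2⁴ factorial around the canonical
  parameter set.

## A worked example

```r
library(soprec)

# spontaneous object recognition, conceptual timeline:
# sample (5 min), ISI (2), sample (5), RI (2), test (5)
run_preset(conceptual_preset("sor"))
#> Preset 'conceptual_sor' (2 counterbalanced runs)
#>   mean peak A1 at test:
#>     novel              0.7320  (spread 0)
#>     recent_in_place    0.2325  (spread 0)
#>   contrasts (delta = Q - P):
#>     novel_vs_familiar        delta +0.4995  ratio 3.148
```

The novel object reaches a peak A1 of 0.73 — most of its elements were
inactive and available — while the familiar object, primed both by its own
recent presentation and by the context it was sampled in, only reaches
0.23.  The model predicts roughly a three-to-one exploration preference for
the novel object.  The same call with `empirical_preset("good_sor")`
reproduces the multi-task battery version (20-min habituation, tiled
contexts, objects in the final half of each context window), averaged over
its four context-order permutations:

```r
run_preset(empirical_preset("good_sor"))
#>   mean peak A1 at test:
#>     P                  0.2568  (spread 0.19)
#>     Q                  0.7312  (spread 0.00051)
#>   contrasts (delta = Q - P):
#>     novel_vs_familiar        delta +0.4744  ratio 2.848
```

Mapping activations to seconds and quantifying robustness:

```r
rec <- generate_synthetic_studies(k_true = 50, n_studies = 4,
                                  noise_sd = 2, seed = 1)
fit <- fit_k(rec)                  # WLS scaling constant (s per A1 unit)
exact_study_bootstrap(rec)$ci      # 95% CI from all 256 resamples

run_local_factorial("sor", delay_minutes = 2)   # ±10% local robustness
run_psp(n_points = 2000, n_runs = 2, seed = 1)  # outcome-region volumes
run_sobol("rr", delay_minutes = 2, seed = 1)    # variance decomposition
```

A thin command-line interface over the same functions lives at
`inst/cli/sop.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sop.R",package="soprec"))')" \
    simulate --preset good_sor --out results/
```

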