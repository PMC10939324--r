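# reachmetrics

Kinematic and surface-EMG analysis of robot-supported upper-limb reaching
sessions, with a fully programmable synthetic-session generator.

## The problem

In robot-assisted reaching exercises performed in a virtual-reality
workspace, a participant repeatedly reaches to a target ball that appears
at one of eight locations and disappears on hand contact. Sessions are run
under different terminal-feedback conditions (visual, haptic, multimodal)
and two target sizes, organised as baseline / training / retention blocks.
Researchers ask whether feedback modality and object size change the
movement strategy — visible in the velocity profile of each reach and in
the timing of muscle activation.

`reachmetrics` implements the full measurement chain for this task:

* **Synthetic sessions** (`sim_config()`, `simulate_session()`): reaches
  modelled as a minimum-jerk ballistic submovement plus corrective
  submovements, five-channel EMG synthesised as envelope-modulated
  band-limited noise with programmable per-muscle latencies, and a
  protocol-structured event log (blocks of 16/24/16/24/16/24/16 segments
  per ball mode). Ground truth is recorded for every programmed quantity.
* **Session I/O** (`read_trajectory()`, `read_emg()`, `read_events()`, and
  writers): versioned plain-text formats.
* **Segmentation** (`segment_session()`, `first_segment()`): event-driven
  cutting of the trajectory into movement segments.
* **Kinematics** (`speed_profile()`, `analyze_kinematics()`,
  `summarize_features()`): the five per-segment variables — movement time
  `t`, mean velocity `v_avg`, peak velocity `v_peak`, time to peak, and the
  velocity peak number `N_peak`, a smoothness index counting speed maxima
  that rise more than 20 mm/s above the preceding minimum and are at least
  150 ms apart.
* **EMG** (`preprocess_emg()`, `peak_latency()`): zero-phase Butterworth
  band-pass (20–400 Hz) plus 50 Hz notch, moving-RMS envelope, and the peak
  latency — the time from target appearance to the envelope peak within the
  first movement segment.
* **Statistics** (`rm_anova2()`, `mauchly_rm()`, `posthoc_bonferroni()`,
  `power_check()`): two-way repeated-measures ANOVA (ball size × condition
  cell) with Mauchly's sphericity test and Greenhouse–Geisser correction,
  Bonferroni-corrected post-hoc paired t-tests, and a Monte-Carlo
  calibration/power harness for the whole pipeline.
* **Orchestration** (`run_config()`, `run_pipeline()`): one-call
  simulate → analyze runs with CSV tables and a JSON manifest; identical
  seed and configuration give byte-identical outputs.

The model at the core: a point-to-point minimum-jerk reach of distance $D$
and duration $T$ follows $x(s) = D\,(10s^3 - 15s^4 + 6s^5)$, $s = t/T$,
with a bell-shaped speed profile peaking at $1.875\,D/T$ at $t = T/2$.
Corrective submovements appended after the primary reach create the extra
velocity peaks that the smoothness count measures, and the condition means
feed the within-subject ANOVA
$y_{sij} = \mu + \pi_s + \alpha_i + \beta_j + (\alpha\beta)_{ij} +
\text{subject-interaction errors}$.

## Worked example

```r
library(reachmetrics)

cfg <- sim_config(n_participants = 3)
ses <- simulate_session(cfg, participant = 1, seed = 42)
ses
#> <sim_session> participant 1 seed 42
#>    272 segments; 82329 trajectory samples; 823285 EMG samples

feats <- analyze_kinematics(ses$trajectory, ses$events)
feats$participant <- 1
summarize_features(feats)
#> # A tibble: 8 x 9
#>   participant ball_mode cell     movement_time  v_avg v_peak time_to_peak n_peak
#>         <dbl> <chr>     <chr>            <dbl>  <dbl>  <dbl>        <dbl>  <dbl>
#> 1           1 big       TH                2.67 0.0350  0.204         2.17   2.69
#> 2           1 big       TM                2.43 0.0341  0.177         2.09   2.19
#> 3           1 big       TV                2.62 0.0344  0.200         2.27   2.12
#> 4           1 big       baseline          3.59 0.0322  0.225         2.75   3.88
#> 5           1 small     TH                2.49 0.0422  0.230         2.13   2.44
#> 6           1 small     TM                2.57 0.0391  0.217         2.15   2.62
#> 7           1 small     TV                2.93 0.0436  0.252         2.26   3.75
#> 8           1 small     baseline          3.24 0.0440  0.279         2.41   4.25
```

Each row is one analysis cell: e.g. in the big-ball condition this
participant's baseline reaches took 3.59 s on average with 3.88 velocity
peaks, while retention reaches after haptic training (TH) took 2.67 s with
2.69 peaks — faster and smoother, the direction of the programmed feedback
effect. Peak latencies per muscle, and the cohort-level ANOVA:

```r
peak_latency(ses$emg, ses$events, ball_mode = "big", cell = "baseline")
#> # A tibble: 5 x 6
#>   muscle            latency peak_time trial ball_mode cell
#>   <chr>               <dbl>     <dbl> <int> <chr>     <chr>
#> 1 biceps brachii       2.56      3.06     0 big       baseline
#> 2 triceps brachii      2.73      3.23     0 big       baseline
#> 3 upper trapezius      2.47      2.97     0 big       baseline
#> 4 anterior deltoid     2.51      3.01     0 big       baseline
#> 5 posterior deltoid    2.64      3.14     0 big       baseline

summaries <- simulate_cohort_features(sim_config(n_participants = 10), seed = 1)
fit <- rm_anova2(rm_dataset(summaries, response = "movement_time"))
tidy(fit)[, 1:5]
#> # A tibble: 3 x 5
#>   effect           df1   df2      F        p
#>   <chr>          <dbl> <dbl>  <dbl>    <dbl>
#> 1 ball_mode          1     9   1.41 2.65e- 1
#> 2 cell               3    27 585.   1.15e-24
#> 3 ball_mode:cell     3    27  40.5  3.90e-10
```

The upper trapezius peaks first (its programmed activation is the most
anticipatory), and the feedback-cell effect on movement time is strongly
detected across the simulated cohort. `autoplot()` on a speed profile marks
the counted peaks; `plot_condition_summary()` and `plot_latencies()` show
cohort summaries.

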