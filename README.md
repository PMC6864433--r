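# fatiguecps

Classification of running fatigue from surface electromyography (sEMG),
anchored on change-point segmentation of the blood-lactate curve.

## The problem

During an incremental treadmill test, blood lactate traces out three
phases: an **aerobic** phase where production and clearance balance, an
**anaerobic** phase where lactate accumulates from the lactate threshold
(LT) up to its maximum at exhaustion, and a **recovery** phase where it
clears again. Lactate sampling needs finger-prick blood every couple of
minutes — useless for everyday training. Wearable sEMG sensors, by
contrast, record continuously, and fatigue alters the sEMG signal: spectral
content shifts, amplitudes drift, activation timing changes.

`fatiguecps` is for exercise physiologists and sports-technology engineers
who want to train and evaluate models that read the fatigue phase off the
sEMG. It implements the full pipeline:

1. **Preprocessing** — zero-phase order-10 Butterworth band-limiting
   (20 Hz high-pass, 400 Hz low-pass at 1926 Hz sampling), implemented as
   numerically robust second-order sections.
2. **Burst detection** — linear-envelope derivative extrema give the
   activation A(i) and deactivation D(i) of each muscle burst; stride
   cycles are anchored on right-biceps-femoris activations.
3. **Features** — per burst, 36 frequency-domain descriptors of the
   normalized power density D(f) = P(f) / ∫P(f)df (mode, mean, SD,
   skewness, kurtosis, deciles q_0.1…q_0.9, and 19 overlapping
   23.44 Hz band powers from 23.44–46.88 Hz to 234.4–257.8 Hz); per
   stride, phase shifts Ø_X,Y = (A_Y − A_X)/stride, active-time
   percentages α_X = (D_X − A_X)/stride and cycle RMS ρ_X, aggregated to
   the 51-entry time-domain / 36-entry time-event session vectors with
   right–left asymmetries.
4. **Lactate change-point segmentation (CPS)** — the connected
   three-segment line l(t) with breakpoints (t′, t″) minimizing
   Σᵢ (l(tᵢ) − x(tᵢ))², solved exactly by exhaustive breakpoint search
   with per-pair least squares; t′ is the LT, t″ the maximal accumulation;
   classes 1/2/3 are assigned by timestamp.
5. **Model building** — Spearman-threshold feature selection
   (|r_s| ≥ τ, τ = 0, 0.05, …, 1), random forests (100 trees × 10 seeds)
   with out-of-bag evaluation: per-class one-vs-rest ROC AUC
   (classification) or R² = 1 − Σ(Y−Ŷ)²/Σ(Y−E[Y])² (regression), and
   Kruskal–Wallis validation of selected features across classes.
6. **Synthetic sessions** — a generator with exact ground truth
   (stride clock, BF→VM→VL firing order, carrier bands, class-dependent
   spectral/amplitude effects on the vastus lateralis, three-phase lactate
   profiles), so the whole pipeline is testable without clinical data.

## Worked example

Simulate a 10-minute session with known breakpoints at 240 s and 480 s,
segment the lactate curve, and classify fatigue from the right vastus
lateralis channel:

```r
library(fatiguecps)

sp  <- session_spec(duration = 600, lactate_breaks = c(240, 480),
                    lactate_interval = 60, channels = "RVL", seed = 7)
ses <- gen_semg_session(sp)      # recording + ground-truth event table
lac <- gen_lactate_profile(sp)   # noisy lactate samples + true breakpoints

fit <- fit_change_points(lac$series)
fit
#> <cps_fit> t' = 360.0 s, t'' = 480.0 s (t_max 600.0 s), sse = 0.8945
#>   slopes (mmol/L/min): 0.147, 0.534, -0.329

rep <- run_pipeline(ses$recording, lac$series, run_config(seed = 7))
rep
#> <model_report> classify / frequency, 545 rows x 36 features
#>   CPS: t' = 360 s, t'' = 480 s
#>   best tau = 0.10 (29 selected)
#>   OOB AUC per class: 1=0.892 2=0.865 3=0.998 (macro 0.918)
```

Reading the output: the fitted breakpoints recover t″ exactly and place t′
two sampling intervals late (measurement noise is 0.3 mmol/L against a
0.05 mmol/L/min aerobic slope); the slope pattern — shallow rise, steep
accumulation, negative recovery — is the expected three-phase shape, and
no plausibility warning fires. The selection sweep keeps 29 of 36
frequency features at τ = 0.10, and the out-of-bag one-vs-rest AUCs show
all three phases are recovered from the sEMG alone, the anaerobic phase
being the hardest (its boundary rows carry label noise from the CPS fit).

A thin command-line wrapper over the same functions ships in
`inst/cli/fatigue-cps`:

```sh
Rscript inst/cli/fatigue-cps simulate --out session/ --seed 7
Rscript inst/cli/fatigue-cps segment-lactate --lactate session/lactate.csv
Rscript inst/cli/fatigue-cps run --semg session/semg.csv \
    --lactate session/lactate.csv --out results/ --mode classify --seed 7
```

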