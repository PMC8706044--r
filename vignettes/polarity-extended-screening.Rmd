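---
title: "Hidden-target screening for polarity-extended LC-MS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden-target screening for polarity-extended LC-MS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarscreen)
```

# The problem

Untargeted plant metabolomics on a serially coupled RPLC–HILIC
("polarity-extended") separation produces per-injection feature tables —
(m/z, retention time, intensity) triples — covering very polar to nonpolar
analytes in one run. Hydrophilic compounds (LogD(pH 7) < 0) elute from the
HILIC column between roughly 5 and 15 min; lipophilic compounds (LogD ≥ 0)
elute from the C18 column after 15 min. `polarscreen` implements the
annotation workflow that turns such feature tables into ranked, eventually
standard-confirmed compound identifications, together with the OPLS-DA
machinery used to compare metabolic profiles across two mass-spectrometer
systems.

The workflow is, in order:

1. **QC against spiked internal standards** — twelve substances at 5 µM in
   every sample and blank; per standard the mean observed m/z, its signed
   ppm deviation from the expected mass, and the retention-time SD across
   all runs are reported. The run passes QC when every sufficiently
   observed standard satisfies |Δppm| ≤ 5 and RT SD ≤ 0.3 min.
2. **Triplicate consensus** — a feature is accepted only if found in all
   three injections of an extract within 5 ppm and 0.3 min.
3. **Blank subtraction** — consensus features matching a blank feature of
   the same solvent are deleted.
4. **Partition at 15 min** into HILIC and RPLC regimes (the retention
   window 5–34 min is applied first).
5. **Retention-time-index (RTI) calibration** — ordinary least squares of
   LogD(pH 7) on retention time over a reference-standard mixture in the
   RPLC regime, so a feature's RT can be converted into a predicted LogD.
6. **Hidden-target screening** — candidates from a compound database within
   5 ppm of the feature's [M+H]⁺ mass, scored by a composite of mass,
   RTI and MS/MS sub-scores; one best ("look at") candidate per feature;
   then successive elimination by the LogD-sign filter and the
   chemotaxonomy filter.
7. **Identification levels** — surviving candidates confirmed with
   reference standards are level 1; the annotation evidence otherwise maps
   onto levels 2–5.
8. **OPLS-DA** — the sample × feature matrix is modelled with the
   instrument as class; the S-plot's correlation loading p(corr) ranks
   features as discriminating (|p(corr)| large) or common to both
   instruments (|p(corr)| small).

# Scoring model

For a feature with ion mass $m$ and a database compound with [M+H]⁺ mass
$m_c$ the signed mass deviation is
$\mathrm{ppm} = (m_c - m)/m_c \times 10^6$. Candidates satisfy
$|\mathrm{ppm}| \le 5$ and receive the linear mass sub-score
$s_\text{mass} = 1 - |\mathrm{ppm}|/5$. The RTI sub-score is a bounded
linear ramp $s_\text{rti} = \max(0,\, 1 - |\hat L - L_c|/2)$ in the
difference between the calibration-predicted LogD $\hat L$ and the
database LogD $L_c$; the MS/MS sub-score is the fraction of the compound's
characteristic fragments matched by intensity-filtered spectrum peaks
(closest-m/z assignment, one peak per fragment, 50 mDa tolerance, 50-count
intensity threshold). The composite is

* HILIC regime: $100 \times (\tfrac12 s_\text{mass} + \tfrac12 s_\text{msms})$
* RPLC regime: $100 \times \tfrac13 (s_\text{mass} + s_\text{rti} + s_\text{msms})$

The functional forms of the mass and RTI sub-scores are this package's own
declared choices: a bounded linear penalty is transparent, monotone, and
easy to audit; both scales (`ppm_window`, `rti_scale`) are configurable.
An absent sub-score (e.g. no MS/MS on a single-TOF instrument) contributes
0 at its nominal weight by default — the conservative reading — with a
renormalizing mode available (`scoring_config(absent_subscore =
"renormalize")`).

# Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `ppm_tol` / `ppm_window` | 5 | ppm | QTOF mass accuracy; also the confirmation bound |
| `rt_tol` | 0.3 | min | replicate RT stability observed with internal standards |
| `rt_window` | 5–34 | min | usable elution window of the coupled separation |
| `noise_threshold` | 50 | counts | peak-picking noise floor |
| `blank_factor` | 1 | – | blank subtraction multiplication factor |
| `msms_mz_tol` | 0.05 | Da | fragment matching (50 mDa) |
| `msms_intensity_threshold` | 50 | counts | separates fragment signal from noise |
| `rti_scale` | 2 | LogD | RTI ramp width; ~residual spread of the calibration |
| `id_rt_tol` | 0.5 | min | level-1 confirmation; a permissive 1.0-min preset accommodates validated glycosides with larger shifts |
| `id_ppm_tol` | 5 | ppm | level-1 confirmation |
| `min_frag_overlap` | 1 | fragments | at least one characteristic fragment confirmed |
| `pcorr_max` | 0.1 | – | "small" |p(corr)| for common features; declared, not fitted |

A `tolerances(preset = "wide")` variant (10 ppm, 3 min, 1000-count filter)
mirrors looser single-TOF vendor settings; its internal vendor semantics
are not reproduced.

# What the synthetic generator emulates

The generator produces the statistical structure the downstream analysis
assumes, with known ground truth:

* compound databases with bimodal LogD (a hydrophilic mode strictly below
  0 and a lipophilic mode above 0, mixing weight `p_polar`), 1–2 plant
  families per compound, and 2–8 characteristic fragments below the
  precursor mass;
* triplicate injections with Gaussian ppm-scale mass error and RT jitter,
  per-injection Bernoulli detection, and log-normal intensities whose
  log-mean differs by extraction solvent;
* two instrument profiles: "A" (detection probability 0.85, no MS/MS,
  lower sensitivity) and "B" (0.95, MS/MS) — the screening prefers B;
* blank contaminants present in blanks and samples alike, and the 12
  internal standards spiked into every table;
* MS/MS spectra containing all true fragments above the intensity
  threshold plus uniform sub-threshold noise peaks.

Retention times derive from a deterministic elution model: the RPLC branch
is linear, `rt = 15 + 4·logd` (capped at 34 min), so that a noise-free
calibration fit is exactly invertible; HILIC retention times are drawn
uniformly in [5, 15) because the workflow uses only the LogD *sign* in
that regime — HILIC RT carries no calibration information. Only the
[M+H]⁺ species is simulated; multi-adduct simulation, isotope patterns and
scan-level chromatograms are out of scope. Abundance distributions and
matrix-effect magnitudes are not published for this kind of data, so all
noise parameters are documented configurables, not measured values.

Consequently, passing tests demonstrate the *mechanics* of the workflow —
filters, scores, calibration, audit trails — under controlled noise; they
do not demonstrate performance on real chromatograms, where peak-picking
artifacts, adduct multiplicity, in-source fragmentation, and correlated
matrix effects all degrade recovery.

The default study (50 truth compounds, 100 decoys, 3 solvents, 2
instruments, 3 injections, 25 contaminants) runs in about a second. Decoy
database entries inherit a truth compound's mass and LogD exactly but
carry foreign families and their own random fragment lists, so they pass
mass screening and the LogD filter and must be caught by chemotaxonomy
alone — the hardest case for that filter.

# Numerical and procedural choices

* **Consensus grouping** is greedy, seeded by descending intensity with
  ties broken by ascending m/z; each injection contributes its closest-m/z
  in-tolerance feature. The alignment software behind published feature
  tables does not document its algorithm; a deterministic, auditable
  greedy scheme was chosen and is verified against an exhaustive
  enumeration oracle on random tables.
* **Blank matching** is coordinate-only at `blank_factor = 1`: any blank
  feature within tolerance deletes the sample feature. An intensity-ratio
  mode (`mode = "ratio"`: delete only if `blank × factor ≥ sample`) is
  provided since published descriptions do not say which semantics the
  vendor software applies. Scan-domain subtraction offsets have no
  feature-table analogue and are not emulated.
* **Consensus m/z and RT** are unweighted means over the replicate
  members (intensity weighting would bias toward the seed injection).
* **The 15.0-min boundary** belongs to the RPLC regime — arbitrary but
  fixed.
* **LogD 0 on HILIC is retained** (elimination is strictly LogD > 0);
  on RPLC, LogD ≤ 0 is eliminated — the two filters are exact
  complements, and commute with the chemotaxonomy filter.
* **Elimination is tagging, not deletion**, so the per-stage audit
  (candidates → look-at → LogD → chemotaxonomy) can be recounted from the
  retained hit list.
* **Look-at ties** break by smaller |ppm|, then lexicographic compound id;
  exactly one look-at hit per feature (a threshold-based multi-hit mode
  was considered and rejected as unspecified).
* **Calibration** refuses non-positive slopes and degenerate designs; with
  no calibration available, RPLC scoring degrades to the 50/50 mass+MS/MS
  weighting with a warning rather than failing.
* **OPLS-DA** is NIPALS PLS2 on the class dummy matrix with orthogonal
  components extracted before the predictive ones (weight = X-loading
  minus its projection on the Y-predictive weight). At zero orthogonal
  components it reduces to standard PLS2, which is verified against an
  independent implementation. Scaling defaults to mean-centering +
  unit variance (the convention of the usual commercial tool), with
  Pareto and `log10(1+x)` as options; constant columns are dropped with a
  warning. Cross-validation uses 7 class-stratified folds (reduced with a
  warning when a class is smaller), scaling re-estimated per training
  fold, and Q² = 1 − PRESS/SS around the training class means. Multi-class
  problems use one dummy-Y model rather than pairwise models.
* **Problem sizes in tests**: oracle equivalence uses 1000 random
  instances of ≤50 features; the PLS limit check uses 50 random 16×12
  matrices; the Q² null calibration uses 100 pure-noise 21×30 datasets.
  These sizes make the checks statistically meaningful while keeping the
  default test run fast.

# Known limitations

* Published dataset-level numbers from real polarity-extended studies
  (feature counts per extract, platform candidate counts, the R²Y/Q²
  values of models on thousands of real features) depend on raw data and
  a live compound database that are not redistributable; this package
  reproduces the *procedures* and verifies them on in-package tables and
  synthetic ground truth instead.
* The scoring sub-score shapes stand in for an unpublished platform
  scoring function; rankings are comparable, absolute scores are not.
* No in-silico fragmentation: database fragment lists replace predicted
  spectra, with a hook for an external predictor.
* No pH-dependent LogD computation; database LogD(pH 7) values are taken
  as given.
* A single ion species ([M+H]⁺) is assumed throughout scoring.

# A worked micro-example

```{r example}
db <- generate_compound_db(20, family_pool = "Lemnaceae", seed = 7)
truth <- generate_ground_truth(db, solvents = "100% MeOH", seed = 8)
des <- study_design(solvents = "100% MeOH",
                    instruments = default_instruments()["B"], seed = 9)
tabs <- simulate_feature_tables(des, db, truth)
cf <- consensus_features(tabs$samples, tolerances())
cf <- blank_subtract(cf, tabs$blanks[[1]], tolerances())
parts <- partition_by_column(cf, tolerances())
nrow(parts$hilic); nrow(parts$rplc)

cal <- fit_calibration(data.frame(rt = truth$compounds$true_rt[db$logd_ph7 >= 0],
                                  logd_ph7 = db$logd_ph7[db$logd_ph7 >= 0]))
cal
```

The full study — screening, identification and OPLS-DA — is one call:

```{r full}
res <- run_study(study_config(seed = 1))
res
head(res$screening$audit)
```
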