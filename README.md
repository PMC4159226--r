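# sigwhistle

Identification and characterisation of bottlenose dolphin **signature
whistle types** from human-annotated time–frequency whistle contours.

Every bottlenose dolphin develops a learned, individually distinctive
signature whistle that broadcasts its identity and serves as a contact
call. In single-hydrophone recordings of freely interacting wild
dolphins, no whistle can be attributed to an individual directly — but
signature whistles can be picked out of the repertoire by their temporal
production alone, because they are repeated in bouts with inter-whistle
intervals (IWIs) of 1–10 s. This package implements that pipeline for
bioacousticians working downstream of visual contour annotation:

* **Whistle assembly** — merge contours broken by <0.03 s silences,
  chain loops separated by 0.03–0.25 s into single-element (SE),
  connected (CML) and disconnected multi-loop (DCML) whistles, gate
  non-identical loop pairs on 80% co-occurrence.
* **REWT catalogue** — flag repeatedly emitted whistle types (≥2
  emissions 0.25–10 s apart in a recording section), remove overlapping
  same-type copies (keep the first, drop the later), and summarise
  per-type occurrence (category size, single-occurrence days, years,
  sites, loop-structure split).
* **SIGID** — a REWT is a signature whistle type when ≥4 whistles occur
  in one encounter and, on at least one occasion, a sequence of ≥4 has
  ≥75% of its whistles within 1–10 s of a same-type neighbour
  (preceding *or* following). Bout census, IWI statistics over
  uncapped measurement bouts with boat-noise exclusion, and inter-loop
  interval (ILI) statistics.
* **Acoustic parameters** — per-whistle start/end/min/max/peak
  frequency, range, duration, inflection count and start/end slope
  aspect; per-type mean ± SD (CV = SD/mean × 100) over runs of 4–10
  consecutive high-quality whistles; unweighted population summaries.
* **Agreement** — Fleiss' kappa κ = (P̄ − P̄ₑ)/(1 − P̄ₑ) with the
  Fleiss (1971) large-sample Z for multi-judge visual classification
  tasks, stage-1→stage-2 consistency and reference-label agreement.
* **Diversity GAMs** — per-encounter signature-type diversity modelled
  against group size (penalized cubic regression spline, GCV), calf
  presence and recording effort with `mgcv`, Gaussian/identity link,
  nested-model ANOVA comparison.
* **Synthetic data** — a seeded generator producing complete annotated
  datasets (templates, bout-structured emission, copies, SNR/masking,
  boat noise, encounter covariates) so the whole pipeline is testable
  without field recordings.

## Worked example

The package ships the published Walvis Bay catalogue summary (28
signature whistle types identified from ~79 h of recordings over
2009–2013) as a reference table:

```r
library(sigwhistle)
s <- summarize_catalogue(walvis_catalogue())
```

```
28 whistle types, 820 whistles in total
category size 29 +/- 20 (max 81)
82% in 2+ years, 93% in 2+ encounters, 4 types at both sites
```

i.e. 820 whistles were classified into 28 types averaging 29 ± 20
members; most types recurred across years and encounters (evidence of
whistle stability), and 4 were recorded at both field sites ~450 km
apart.

A full synthetic analysis, from contours to the diversity model:

```r
ds  <- generate_dataset(n_encounters = 30, seed = 7)
res <- run_whistle_pipeline(ds$contours, ds$encounters)
res$gam_comparison$ranking
```

```
catalogue types: 42   signature types: 28
  model       aic       gcv  dev_expl  best
1     1 104.25378 1.7775473 0.4434516 FALSE
2     2 104.25378 1.7775473 0.4434516 FALSE
3     3  83.83484 0.9054458 0.7363938  TRUE
population mean ILI 0.13 s over 62 intervals
```

The pipeline rebuilt a 42-type catalogue, flagged 28 signature types
(exactly the planted ones; none of the planted non-signature REWTs were
flagged), and the best diversity model — calf presence plus a smooth of
group size — explains 74% of the deviance in this synthetic dataset,
recovering the generator's built-in increase of signature-type
diversity with group size and calf presence. `res$catalogue`,
`res$params`, `res$iwi` and `res$ili` hold the catalogue-, parameter-
and temporal-summary tables.

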