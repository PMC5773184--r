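# phasevar

Decomposing the sources of phase variability in rhythmic motor systems
that alternate between two coordination states.

## The problem

Rhythmic motor systems — the leech heartbeat being the canonical example —
produce stereotyped output whose timing nevertheless varies considerably
across individuals. In that system, a central pattern generator (CPG) of
bilaterally paired heart interneurons drives segmental heart motor neurons
and, through them, the two heart tubes. One body side beats in a
rear-to-front *peristaltic* coordination while the other beats nearly
*synchronously*, and the sides swap states every 15–60 beat cycles. The
key output variable is the intersegmental phase difference Δφ — the
offset between a front and a rear segment's activity markers as a fraction
of the beat period.

`phasevar` turns spike trains (or constriction traces) into per-cycle Δφ,
segments them into coordination episodes and switch cycles, and asks where
the variability of Δφ lives, at four nested levels:

| level | statistic |
|---|---|
| cycle-to-cycle | angular variance of Δφ within an episode |
| repetition | variance of ΔΔφ = Δφ₁ − Δφ₂ across consecutive switch cycles |
| bilateral | variance of ΔΔφ = Δφ_L − Δφ_R within animals |
| population | angular variance of per-animal mean Δφ |

All dispersion is circular: phases are summed as unit vectors, the mean
resultant length *r* gives the angular variance *s*² = 2(1 − *r*) (rad²; divided
by 4π² for phase² units). Inference uses studentized bootstrap confidence
intervals for population variances and scrambling (cross-animal
re-pairing) null distributions with z-score p values for the repetition
and bilateral levels. A spike-triggered-averaging module estimates
synaptic conductances from voltage-clamp traces (g = I/(V_hold − E_rev),
E_rev = −62 mV) and compares bilateral proportional strengths
g₄/(g₄+g₇). A hierarchical synthetic-data generator with known ground
truth stands in for animal recordings and backs every test.

## Worked example

```r
library(phasevar)

cfg <- generator_config(n_animals = 12, seed = 42)   # synthetic study
pop <- generate_population(cfg)                       # spike trains + truth
res <- analyze_recordings(pop$recordings,
                          analysis_params(n_boot = 2000, n_scramble = 2000,
                                          seed = 42))

subset(res$population, level == "cpg" & coordination == "peristaltic" &
       side == "L" & switch_cycle == 1)
#>  level coordination side switch_cycle  n mean_dphi         s2       ci_lo      ci_hi
#>    cpg  peristaltic    L            1 10 0.2574324 0.01113967 0.007363124 0.02057714
```

Ten usable animals; the left-side peristaltic CPG pattern has a mean
intersegmental Δφ of 0.257 (the generator's 0.23 plus sampling noise at
n = 10) and a population angular variance of 0.011 phase² with a 95%
bootstrap CI of [0.0074, 0.021].

```r
subset(res$repetition, level == "cpg" & coordination == "peristaltic" & side == "L")
#>  level coordination side  n     observed  null_mean         z            p
#>    cpg  peristaltic    L 10 0.0004887582 0.02216986 -3.589179 0.0001658606
```

The variance of ΔΔφ between consecutive switch cycles (0.00049 phase²) is
far below the scrambled cross-animal expectation (0.022 phase²): repeating
the same coordination minutes later is much more precise than the
population spread, p ≈ 1.7 × 10⁻⁴ (one-sided, z score against 2,000
scrambled populations).

```r
circular_summary(c(0.18, 0.22, 0.21, 0.25, 0.2))
#> Circular summary (n = 5)
#>   mean phase: 0.2120  r: 0.9895
#>   angular variance s^2: 0.0210785 rad^2 = 0.000533925 phase^2
#>   angular SD s: 0.145184 rad = 0.0231068 phase
```

`res$components` adds the method-of-moments decomposition of all four
variance components per level and coordination, and `run_pipeline()` /
`simulate_run()` provide the same analysis over delimited files on disk
with a manifest and byte-reproducible reports. A thin command-line wrapper
lives at `inst/cli/phasevar.R`. The methods vignette
(`vignettes/phase-variability-methods.Rmd`) documents the model, the
segmentation algorithm, and every numerical choice.

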