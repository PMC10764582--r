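# mird — retrieved-dropout multiple imputation for time-to-event endpoints

`mird` is an R package for sensitivity analysis of time-to-event
endpoints in outcome trials (the motivating setting is a cardiovascular
outcome trial with a time-to-first-MACE endpoint) when some subjects
leave the study before an event. The usual Cox analysis censors those
subjects at dropout and assumes the censoring is non-informative; when
dropout may be treatment-related, that assumption is fragile. `mird`
instead multiply-imputes the missing event/censoring times under a
neutral missing-not-at-random assumption: **subjects who drop out behave
like the retrieved dropouts (RDs) of the same randomized arm** — the
subjects who also discontinued treatment but stayed under observation,
so their outcomes are known.

## The method in brief

For a dropout censored at `c` with covariates `Z`, draw `u ~ unif(0,1)`
and solve the conditional-survival identity

    S(t | Z) / S(c | Z) = u,   t > c,

where `S` is fitted **to the RD subset only**. Three flavors of `S` are
provided, plus a comparator:

| method | model for S | inversion | uncertainty propagation |
|---|---|---|---|
| `bootstrap` | Cox (semi-parametric) | linear interpolation on a day grid from `c` to the horizon `C` | B bootstrap refits of the RD subset |
| `pwe` | piecewise-exponential PH, hazards `lambda_u` on `[tau_{u-1}, tau_u)` | closed form | MVN draws of `(log lambda, beta)` from the full observed-information covariance |
| `weibull` | Weibull AFT, `log T = gamma0 + Z'gamma + sigma*eps` | `t = (c^(1/sigma) - e^(eta/sigma) log u)^sigma` | MVN draws of `(gamma0, gamma, log sigma)` |
| `j2r` | jump-to-reference (active dropouts follow the placebo law after dropout) | closed form, floored at `c` | as `weibull` |

Imputed times beyond the administrative horizon `C = D - R + 1` become
censored at `C` (with an optional vital-status refinement against death
dates). Each of the `B` completed datasets is analyzed with the regular
Cox model; estimates are pooled by Rubin's rules (total variance
`W + (1 + 1/B) B_var`, t reference with the classical degrees of
freedom). A clinical-trial simulator reproduces the type-I-error and
power operating-characteristic studies of the method.

## Worked example

```r
library(mird)

spec  <- scenario_spec(N_total = 5000, rd_frac = 0.2, disc_frac = 0.15,
                       seed = 7)
trial <- simulate_trial(spec)
classify_disposition(trial)
#> Disposition partition
#>   completers:         3290
#>   retrieved dropouts: 1000
#>   missing data:       710

run_mird(trial, method = "weibull", B = 100, seed = 42)
#> Pooled result over B = 100 imputation(s)
#>   HR 1.0726 (95% CI 0.8930, 1.2884), p = 0.4533
#>   log-HR 0.07012 (SE 0.09350); W = 0.00784, B_var = 0.00089, df = 9355.3
#>   mean events: placebo 246.8, active 264.0
```

This null trial (`hr = 1`) has 710 subjects whose outcomes were never
observed; the Weibull imputer fills them in 100 times from the
RD-fitted conditional distribution. The pooled hazard ratio stays near
1 with a p-value of 0.45, and the fractional "mean events" are the
average post-imputation event counts per arm across imputations. The
plain Cox analysis of the same data (`method = "cph"`, censoring at
dropout) gives HR 1.0861, p = 0.37 — imputation adds events (~511 total
vs 441 observed) while propagating the imputation uncertainty through
`B_var`.

## Command line

```sh
Rscript inst/cli/mird.R analyze  --input trial.csv --method weibull --B 100 --seed 17 --out-dir out/
Rscript inst/cli/mird.R impute   --input trial.csv --method pwe --cuts quartiles --out-dir imputed/
Rscript inst/cli/mird.R simulate --grid grid.json --reps 1000 --out-dir sim/
```

`analyze` writes `pooled_result.json` (byte-identical on rerun with the
same seed), a human-readable `report.txt`, and `run_meta.json` (config
hash, seed, package version, timestamp). `simulate` writes per-method
summary CSVs with Monte-Carlo standard errors and supports
checkpoint/resume. Input tables are delimited text with a documented
column dictionary (`?trial_dataset`); a dialect map renames columns from
ADaM-like exports without code changes.

## Documentation

Function-level documentation is in the roxygen comments in `R/`; the
methods vignette (`vignettes/mird-methods.Rmd`) describes the models,
the day-counting conventions, what the simulator does and does not
emulate, numerical edge-case handling, and the design decisions taken
where the method's description leaves room.
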