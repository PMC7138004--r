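# labmu — top-down measurement uncertainty for clinical laboratories

Accredited clinical laboratories must attach a measurement uncertainty (MU)
to their quantitative procedures, and the practical way to get one is
*top-down*: from the quality-control data the laboratory already produces,
rather than from a component-by-component (GUM) budget. `labmu` implements
that workflow for laboratory physicians, clinical chemists and quality
managers:

* **Imprecision**: the within-laboratory CV, `CV_WL = mean_levels(100·SD/mean)`,
  from internal QC series.
* **Bias**: per-item relative biases `b_i = 100(x_i − a_i)/a_i` from three
  sources — proficiency tests (PT, after discarding rounds with |z| > 2),
  certified reference calibrators (CRC) and inter-laboratory internal QC
  scheme (IQCS) peer comparisons — aggregated as `RMS_bias = sqrt(mean b_i²)`.
* **Bias uncertainty** under three published formulations:
  * *Nordtest*: `u(Bias) = sqrt(RMS² + u(target)²)`, where the target
    uncertainty pools per-round peer standard errors,
    `u(PT) = sqrt(mean(CV_PT,i²/n_lab,i))` (CRC additionally adds the
    certificate term `u(Cal) = (U_cal/k_cal)/assigned`);
  * *Eurolab*: Nordtest plus the replicate term `(CV_rep/√n_rep)²`
    (identical to Nordtest for CRC; not computable for IQCS — no duplicates);
  * *Cofrac*: `u(Bias) = sqrt((half-range/√3)² + SD(b_i)²)` from the spread
    of the biases alone (not applicable to CRC).
* **Combination and expansion**: `u_c = sqrt(CV_WL² + u(Bias)²)`,
  `U = k·u_c` with k = 2.
* **Quality goals**: Westgard desirable allowable total error
  `TEa = 1.65·(0.5·CV_I) + 0.25·sqrt(CV_I² + CV_G²)` and Haeckel-style
  permissible uncertainty derived non-linearly from the reference-interval
  width, with verdicts per budget.
* **Synthetic data**: a generator for all four QC streams with known true
  bias and imprecision, so the whole pipeline is verifiable end to end.

All percentages are percent (9.2 means 9.2%). Statuses are reported
literally: `NC` (no peer group), `ND` (no duplicate results), `NE` (formula
has no bias term for this source).

## Worked example

The package bundles a four-analyte summary-level example
(`inst/extdata/example_summaries.csv`: bias uncertainties per approach ×
source plus CV_WL for CA 19-9, testosterone, ALP and creatinine). From
summaries only the combination and expansion steps run:

```r
library(labmu)
path <- system.file("extdata", "example_summaries.csv", package = "labmu")
budgets <- budgets_from_summaries(path, k = 2)
render_report(budgets)
```

```
      analyte U_nordtest_pt U_nordtest_crc U_nordtest_iqcs U_eurolab_pt U_cofrac_pt
      CA 19-9          25.9           19.0              NC         26.4        40.4
 Testosterone          18.2           20.2              NC         18.7        22.8
          ALP          11.3            9.3            10.5         20.9        12.5
   Creatinine          11.3            8.4             7.0         17.7        18.6
```

Each cell is the expanded uncertainty (%, k = 2) of that approach × source;
e.g. creatinine Nordtest-PT is `2·sqrt(2.0² + 5.3²) = 11.3%`. CRC/IQCS data
give the smallest uncertainties, the Cofrac formula the largest, and the two
immunoassays exceed their permissible uncertainty (16.0% and 13.1%) under
every formula.

The raw-data route is the five scripts under `analysis/`, which simulate a
creatinine-like laboratory (true bias +5.2%, true CV_WL 2.0%), estimate
imprecision and per-source bias, assemble all nine budget cells, and judge
them against goals — run them in order from the repository root:

```sh
Rscript analysis/01_simulate.R        # writes results/data/*.csv
Rscript analysis/02_imprecision_bias.R
Rscript analysis/03_uncertainty_budgets.R
Rscript analysis/04_quality_goals.R
Rscript analysis/05_summary_example.R
```

See `vignettes/top-down-uncertainty.Rmd` for the formulas, the design
choices in their ambiguous corners, and what the synthetic generator does
and does not emulate.

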