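# trafshed

Apportioning street-level traffic emissions to administrative districts and
relating the district totals to mortality rates.

## The problem

Hourly traffic emission inventories report NOx and PM2.5 emissions (g/km)
per *road*, hour of day (0–23) and vehicle type (eight classes: private
car, taxi, SPB, LV, LGV, MGV+HGV, PLB, bus). Health statistics report
deaths per *district*. `trafshed` bridges the two with a geo-processing and
data-analytic pipeline:

1. **Allocation.** Each road polyline is clipped against the district
   polygons; the clipped planar length *d_A* over the source geoid length
   *d_G* gives the ratio *R = d_A / d_G*, the portion emission is
   *E_A = R · E_O*, and district totals sum over roads and vehicle types,
   *E = Σᵢ Σⱼ E_{A j,Vᵢ}*. Duplicate source records of one road are
   dissolved per (road, district); single-district roads get *R* = 1
   exactly. A strict "geoid length > 1 m" filter cleans the raw network.
2. **Hours.** Four case studies: all 24 hours (1); the fixed 5-hour rush
   set {7, 8, 9, 17, 18} (2); refined 12-hour sets depending on the
   district's residential group — {5–9, 14–20} for residential districts
   (population share ≥ 6 %), {5–10, 14–19} otherwise (3, 4).
3. **Activity buffer.** Case 4 keeps only roads within 0.2 km of the union
   of building/podium footprints (the potential human-activity region),
   represented exactly as a Minkowski dilation.
4. **Association.** Ordinary least squares of the district mortality rate
   (deaths per 100,000 over a pollutant-specific ICD-10 catalogue, averaged
   over 2015–2018) on the district emission total, reporting Pearson *R*,
   RMSE and the zero-slope *p*-value, overall and per district group.
5. **Outliers.** With the case-4 line, the percentage deviation
   *PD = (MRP − MRA)/MRA · 100* of each district is compared against the
   band *mean(PD) ± SD(PD)*; districts outside it are flagged as having
   mortality in excess of, or below, what their traffic emissions predict.

Because the kind of data this pipeline consumes is typically not publicly
deposited, the package ships a first-class seeded synthetic-city generator
(districts, roads, buildings, hourly emission tables with a double-peak
diurnal cycle and realistic vehicle mix, mortality with a planted linear
emission–mortality relation and planted outlier districts) so every stage
is testable end to end. See the methods vignette
(`vignettes/trafshed-methods.Rmd`) for the model, parameters and design
choices.

## Worked example

```r
library(trafshed)
city   <- generate_city(city_config(rng_seed = 7))
report <- run_case_study(4, city)
print(report)
```

```
Case study 4 report
  roads: 226 input, 226 after length filter, 172 considered
  NOx: R = 0.676, RMSE = 20.05, slope = 0.0001403, p = 0.00209 (n = 18)
  PM2.5: R = 0.705, RMSE = 17.98, slope = 0.001733, p = 0.00109 (n = 18)
  NOx outlying districts: D04 (+35.6%), D18 (-65.0%)
  PM2.5 outlying districts: D04 (+33.1%), D18 (-49.9%)
```

The 226 road records collapse to 200 roads (duplicates dissolve); 54
records lie farther than 0.2 km from every building and drop out of the
buffered case study. The regression recovers the planted slope
(`city$config$beta_nox = 1.5e-4`) within sampling error, and the deviation
band —

```r
report$deviations$NOx$thresholds
#> PD thresholds (N = 18): PDA = -2.75%, SD = 18.49%, band [-21.24%, 15.74%]
```

— flags exactly the two planted outlier districts: D04, whose mortality was
shifted +50 % above the planted line (positive PD: mortality exceeds the
prediction), and D18, shifted −35 % below it.

A thin command-line front end over the same functions lives in
`inst/cli/trafshed.R` (`generate`, `validate`, `run --case {1,2,3,4}`).

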