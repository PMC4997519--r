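# netspat

Network-constrained point pattern analysis of urban facilities in R.

Hospitals, clinics and pharmacies are *alongside-network* events: they
sit on streets, and the distances that matter between them run along
streets. Planar density and K-function analysis over-detects clustering
for such events because it ignores that the points are confined to a
one-dimensional subnetwork of the plane. netspat does the whole
analysis in network space:

- **Weighted network kernel density estimation (NetKDE).** Density at a
  network location *s* is

  λ(s) = Σᵢ (1/r) · (1/√(2π)) · exp(−d(s,i)² / 2r²) · Bᵢ,  for d(s,i) ≤ r,

  with *d* the shortest-path network distance, *r* the bandwidth
  (default 600 m) and *Bᵢ* the facility weight (bed count; all 1 in
  unweighted mode). Evaluated on ≤ 20 m lixels, rasterizable.
- **Network auto / cross K-functions** with Monte Carlo CSR envelopes:
  K(t) = (1/ρ)(1/n) Σᵢ n(t|pᵢ), ρ = (n−1)/|S|, envelopes from the
  5th/95th order statistics of 99 network-CSR simulations, and per-bin
  clustered / random / dispersed classification.
- **Street centrality** (multiple centrality assessment): betweenness
  C^B (ordered-pair normalised, tied shortest paths fractionally
  credited), closeness C^C = (N−1)/Σd, straightness C^S = mean
  Euclidean/network distance ratio — plus planar-KDE surfaces of each.
- **Raster Spearman correlation** between facility-category density
  surfaces and centrality surfaces (the 8-category × 3-index table).
- **Synthetic-city generator**: grid networks, CSR / clustered /
  regular / cross-clustered point processes on the network, and
  facility attributes (strength classes 1–5, ownership, skewed bed
  counts), so the full pipeline runs and is tested without proprietary
  GIS layers.

## Worked example

```r
library(netspat)

city <- simulate_city(rows = 12, cols = 12, spacing = 100,
                      n_hospitals = 150, n_pharmacies = 100,
                      hospital_scale = 250, pharmacy_scale = 100, seed = 42)
city$net
#> road_network: 144 nodes, 264 edges, total length 26400 m

kfun <- network_kfun(city$net, city$hospitals, n_sim = 99, seed = 42)
kfun
#> auto K-function: 150 points, 56 distance bins, 99 CSR simulations (alpha = 0.05)
#>   summary pattern: clustered
```

The observed K sits above the CSR upper envelope at small distances:
the generated hospitals cluster along the network, and the analysis
recovers that. Pharmacies seeded around hospitals are likewise detected
by the cross K-function:

```r
crossk <- network_cross_kfun(city$net, city$hospitals, city$pharmacies,
                             n_sim = 99, seed = 43)
classify_pattern(crossk)
#> pattern: clustered ( clustered 44, random 12 )
```

Density, centrality and their correlation on one raster:

```r
field <- normalize_field(netkde(city$net, city$hospitals, bandwidth = 600))
field
#> density_field: 1320 lixels; bandwidth 600 m; weighted (min-max normalized)
#>   lambda range: 0 1

cent <- street_centrality(city$net)
grid <- grid_from_network(city$net, 20)
fields <- facility_category_fields(city$net, city$hospitals, grid)
surfaces <- list(CS = centrality_surface(city$net, cent$cs, 600, grid),
                 CC = centrality_surface(city$net, cent$cc, 600, grid),
                 CB = centrality_surface(city$net, cent$cb, 600, grid))
correlation_table(fields, surfaces)
#>       category    CS    CC    CB
#>    First class 0.692 0.693 0.693
#>   Second class 0.966 0.967 0.968
#>    Third class 0.980 0.981 0.981
#>   Fourth class 0.752 0.753 0.752
#>    Fifth class 0.988 0.989 0.990
#>         Public 0.973 0.974 0.975
#>        Private 0.934 0.934 0.934
#>  All hospitals 0.964 0.965 0.965
```

Each cell is Spearman's r between a facility-category density raster
and a centrality surface over their shared valid cells: in this
simulated city every category follows street structure closely, with
the sparser first/fourth-class subsets correlating least. The full
pipeline (`run_full()`) chains all stages from one seeded
configuration and writes CSV / GeoJSON / ESRI ASCII / JSON outputs.

## Vignette

`vignettes/network-point-patterns.Rmd` documents the estimators, their
assumptions, every default that matters (bandwidth, cell size,
envelope order statistics, the classification summary range), what the
synthetic-city generator does and does not emulate, and known
limitations.
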