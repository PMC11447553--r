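# sclamellar

Analysis toolkit for multilayer **stratum corneum (SC) lipid membranes** —
mixtures of ceramide NS (CER NS), cholesterol (CHOL) and free fatty acid
(FFA) that assemble into stacked lamellae such as the ~5.4 nm short
periodicity phase (SPP). It is written for membrane simulators and x-ray
scattering practitioners who need to ask, of a three-bilayer (six-leaflet)
stack: *do lateral domains of distinct thickness and composition exist, who
neighbors whom once composition is controlled for, how does order melt with
temperature, and what lamellar phases would the diffraction pattern show?*

The package analyses particle configurations (GRO/PDB plus a topology
table, or its own text container); it also ships a synthetic-configuration
generator with exact ground truth (imposed domains, known conformer labels,
known transition temperatures) so that every stage is testable without
molecular-dynamics output.

## What it computes

**Local structure of the central bilayer.** On a G x G grid (default
50 x 50) across the membrane plane, lipids within 0.8 nm (periodic x-y
distance) of each grid point are isolated; the local bilayer thickness is
the distance between the two head-bead density peaks flanking the
central-bilayer midplane, and the local composition is the fraction of each
tail type (CER acyl, CER sphingosine, CHOL, FFA). Pooled histograms,
Pearson/Spearman thickness-composition correlations, and a two-component
Gaussian-mixture "larger vs smaller thickness" domain summary follow.

**Neighbor statistics with a mixing null.** Each lipid tail (the two CER
chains counted separately and labelled extended or hairpin, giving six tail
classes and 21 unordered pair types) is linked to its k = 6 nearest tails
by center-of-mass distance (k = 7 for CHOL). Observed pair frequencies are
divided by the perfectly-mixed expectation

    w(i, j) = N_i * N_j   (i != j),    w(i, i) = N_i (N_i - 1) / 2,

normalized over the 21 pairs, so every value is 1 in a mixed system and
preferred neighbors exceed 1. Composition-normalized coordination numbers
provide the same information per reference tail class.

**Thermotropic metrics.** Nematic order parameter S2 (largest eigenvalue of
the average nematic tensor of 12-carbon-section directors; 1 = aligned,
&lt;0.3 = isotropic), the C-H bond order parameter
S_CH = (1/2)<3 cos^2 theta - 1> in [-0.5, 1], the normalized lipid area
(tails per nm^2 with CHOL weighted 1.9), and the membrane thickness from
half-bulk water-density interfaces — block-averaged in 5 degC windows and
fitted with a continuous two-regime (hinge) model to locate phase
transitions.

**Lamellar scattering math.** Spacings 2*pi/q, repeat distances
d = 2*n*pi/q_n, Pearson VII peak fitting (Levenberg-Marquardt), and greedy
assignment of observed peaks to lamellar phases (shared overlapping orders
allowed, as in commensurate SPP/double-repeat series).

## Worked example

Generate a stack with two imposed half-plane domains (a thin 5.16 nm
CHOL/sphingosine-rich region and a thick 5.78 nm FFA/acyl-rich region),
then recover them:

```r
library(sclamellar)

spec <- synthetic_spec(n_lipids = 600, seed = 11, domain_spec = list(
  list(type = "half_plane", from = 0, to = 0.5, thickness_nm = 5.16,
       enrich = c(CHOL = 2.5, CER_sph = 2.5, CER_acyl = 0.4)),
  list(type = "half_plane", from = 0.5, to = 1, thickness_nm = 5.78,
       enrich = c(FFA = 2, CER_acyl = 2.5, CER_sph = 0.4))))
system   <- make_multilayer(spec)
leaflets <- assign_leaflets(system$frames[[1]], system$topology)
leaflets
#> <sc_leaflets> 6 leaflets at z = 12.85, 18.15, 18.75, 24.55, 25.15, 30.55 nm; central bilayer = (3, 4)

tm <- thickness_map(system$frames[[1]], system$topology, leaflets, G = 30)
cm <- composition_map(system$frames[[1]], system$topology, leaflets, G = 30)
pooled <- pool_grid_data(tm, cm)
print(thickness_composition_correlation(pooled), digits = 2)
#>   tail_type pearson_r spearman_rho   n degenerate
#> 1  CER_acyl      0.40         0.24 900      FALSE
#> 2   CER_sph     -0.54        -0.48 900      FALSE
#> 3      CHOL     -0.45        -0.42 900      FALSE
#> 4       FFA      0.36         0.43 900      FALSE

gmm_domains(pooled, seed = 1)
#> <sc_domains> two-component Gaussian mixture on (thickness, composition)
#>           domain CER_acyl_pct CER_sph_pct CHOL_pct FFA_pct thickness_nm weight
#>           larger           32          24       11      32         5.75   0.55
#>          smaller           24          34       19      24         5.19   0.45
#>  mixture average           28          29       15      29         5.50   1.00
```

The correlation signs (CHOL and sphingosine fractions falling, FFA and acyl
fractions rising with thickness) and the recovered domain means match the
construction: the thin domain is CHOL/sphingosine rich, the thick domain
FFA/acyl rich.

Diffraction peaks at q = 0.58, 1.164, 1.75 and 2.327 nm^-1 decompose into a
doubled-repeat lamellar series and the SPP sharing its even orders:

```r
assign_lamellar_phases(c(0.58, 1.164, 1.75, 2.327))
#> <sc_lamellar>
#>   lamellar phases:
#>     d n_orders  orders                   peaks
#>  10.8        4 1,2,3,4 0.580,1.164,1.750,2.327
#>   5.4        2     1,2             1.164,2.327
```

A shell entry point wraps the same stages
(`exec/sclamellar {generate|thickness|domains|neighbors|thermo|saxd}`),
writing CSV/JSON artifacts plus the verbatim config into an output
directory.

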