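# flavoqsar

Ligand-based discovery of natural α-glucosidase inhibitors among dietary
flavonoids, as a tested, reusable R pipeline.

α-Glucosidase (EC 3.2.1.20) catalyses the final step of carbohydrate
digestion; inhibiting it blunts postprandial hyperglycemia, and dietary
flavonoids are a rich source of mild, low-toxicity inhibitors. `flavoqsar`
implements the complete computational chain used to find new ones:

1. **Fingerprint similarity & clustering** — hashed topological fingerprints
   (all connected subgraphs of 1–7 bonds, 2048 bits) and ECFP-style circular
   fingerprints; Tanimoto similarity `T(A,B) = |A∩B|/|A∪B|`; single-linkage
   hierarchical clustering of compound sets.
2. **2D molecular descriptors** — computed from a hydrogen-suppressed
   molecular graph parsed from SMILES: Moreau–Broto autocorrelations
   `ATS_k(w) = Σ_{d(i,j)=k} w_i w_j` (mass or van der Waals volume weights),
   Basak neighbourhood-symmetry information indices
   (`IC_k = −Σ p_c log₂ p_c`, `CIC_k = log₂N − IC_k`, Brillouin-form `MIC_k`),
   and Kier–Hall electrotopological states
   `S_i = I_i + Σ_j (I_i−I_j)/(d_ij+1)²` with `ssCH2` atom typing.
3. **MLR-QSAR modelling** — OLS multiple linear regression of
   `pIC50 = −log₁₀ IC50[mol/L]` on genetic-algorithm-selected descriptor
   subsets; leave-one-out `Q²`/PRESS, `R²`, adjusted `R²`, RSS, SDEC/SDEP,
   MSE/MAE validation suite; the two published five-descriptor equations
   (`MIC1, ATS4v, AATS7m, CIC3, minssCH2` and the 3D set) are built in.
4. **Virtual screening funnel** — similarity enrichment (> 0.8 to any seed),
   canonical-SMILES deduplication, QED ≥ 0.5 and MW ≤ 650 drug-likeness
   filters, element whitelist, activity prediction and ranking.
5. **MMGBSA bookkeeping** — parse `value ± sd` component tables and audit the
   printed ΔG decomposition (`ΔG_gas = ΔE_vdw + ΔE_ele`,
   `ΔG_sol = ΔG_pol + ΔG_nonpol`, `ΔG_bind = ΔG_gas + ΔG_sol`).
6. **Synthetic data** — seeded generators for correlated descriptor/activity
   datasets with known linear truth, and flavonoid-like screening libraries
   with planted near-duplicates.

There is no cheminformatics toolkit in the dependency set: the SMILES
parser, kekulization/aromaticity perception, canonical writer, fingerprints
and descriptors are implemented here, in base R, and are oracle-tested.

The 27-compound reference set (experimental pIC50 against *S. cerevisiae*
α-glucosidase, with PubChem CIDs and the published per-compound model
predictions) ships as a plain-text fixture: `load_reference_dataset()`.

## Worked example

```r
library(flavoqsar)

ref <- load_reference_dataset()            # 27 flavonoids, Σ pIC50 = 95.314
S   <- similarity_matrix(ref, kind = "path")
cl  <- single_linkage_cluster(S, 6)
ms  <- cluster_mean_similarity(cl, S)

trio <- c("5280441", "56776173", "3084995")   # vitexin, its 4'-O-glucoside,
unique(cl$labels[trio])                        # isoschaftoside: one cluster
#> [1] 4
round(ms[["4"]], 4)
#> [1] 0.9164     # mean within-cluster Tanimoto, the "MFS > 0.9" cluster

published_model_2d()
#> <mlr_model> y = 4.12506 + (-0.15599) x MIC1 + (-0.00011) x ATS4v +
#>   (0.05492) x AATS7m + (3.06615) x CIC3 + (-3.00189) x minssCH2

# GA descriptor selection on a synthetic dataset with 5 planted predictors
d   <- synth_linear_dataset(n = 60, p_total = 40, noise_sd = 0.1, seed = 2024)
sel <- ga_select(correlation_filter(clean_descriptors(d$table)), d$y,
                 k = 5, seed = 11)
sel$subset; round(sel$fitness, 4)
#> [1] "D1" "D2" "D3" "D4" "D5"     # the planted subset
#> [1] 0.9997                       # Q2_LOO

# MMGBSA audit: one printed total is inconsistent with its own components
aud <- audit_energy(load_energy_table())
aud[!aud$pass, c("complex_id", "field", "printed", "aggregated")]
#>       complex_id field printed aggregated
#>  Norartocarpetin g_gas   83.95     -83.95   # sign typo in the source table
```

The cluster mean of 0.9164 says the three C-glycosylflavones form the
tightest structural family in the set; the GA run shows the selector
recovering a known 5-descriptor signal out of 40 candidates; the audit
demonstrates the energy bookkeeping catching a real sign error.

## Command line

An `Rscript` front end is installed at `inst/cli/flavoqsar` with subcommands
`cluster`, `descriptors`, `fit`, `predict`, `screen`, `energy-audit`,
`synth`; run it without arguments for usage.

See `vignettes/methods.Rmd` for the model conventions, parameter choices,
what the synthetic generators do and do not emulate, and known limitations.
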