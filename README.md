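# ceRNAcross

Deterministic modelling of **competing endogenous RNA (ceRNA) crosstalk** on
bipartite miRNA–RNA interaction networks, at system scale.

microRNAs repress their target RNAs by binding and promoting their decay.
Because many transcripts compete for a shared, limited pool of miRNAs, a
change in the transcription of one RNA frees or sequesters miRNA molecules
and thereby perturbs the steady-state levels of every other RNA coupled to it
— directly, through shared regulators, or indirectly, through chains of
miRNA-mediated interactions. `ceRNAcross` quantifies this effect exactly for
arbitrary interactomes and provides the ensemble and null-model machinery
needed to study its statistics, for computational biologists working with
CLASH-style miRNA interactomes or synthetic stand-ins.

## Model

For *N* RNA species (levels *m<sub>i</sub>*) and *M* miRNA species (levels
*μ<sub>a</sub>*) with transcription rates *b<sub>i</sub>*, *β<sub>a</sub>*,
degradation rates *d*, *δ*, association rate
*k<sup>+</sup><sub>ia</sub>* and complex decay through a stoichiometric
(*σ*) and a catalytic, miRNA-recycling (*κ*) channel, mass-action kinetics
admits a unique stable steady state satisfying the coupled titration maps

```
μ_a = μ*_a / (1 + Σ_i m_i / m0_ia),   m_i = m*_i / (1 + Σ_a μ_a / μ0_ia)
```

with *m\*<sub>i</sub> = b<sub>i</sub>/d*, *μ\*<sub>a</sub> = β<sub>a</sub>/δ*
the unrepressed levels and *μ0<sub>ia</sub>*, *m0<sub>ia</sub>* threshold
constants (inverse coupling strengths) tied pairwise by the
stoichiometricity ratio *λ = σ/(σ+κ)*: *μ0/m0 = λ·d/δ* (≈ 0.59 at the
reference kinetics *d* = 0.08/h, *δ* = 0.027/h, *λ* = 0.2).

Crosstalk between RNAs *i* and *j* is measured by the **susceptibility**

```
χ_ij = d_j ∂[m_i] / ∂b_j ,
```

computed exactly by linear response as `χ = (I − W)⁻¹ diag(m/m*)`, where the
coupling matrix `W_ij = (m_i²/m*_i) Σ_{a∈i∩j} (μ_a²/μ*_a)/(μ0_ia m0_ja)` sums
over shared regulators. From χ the package derives the system-level
descriptors studied in the ceRNA literature: mean and maximal pairwise
susceptibility, incoming/outgoing selectivities (inverse participation
ratios), the locality kernel *K<sub>ij</sub>* and its Pearson correlation ρ
with χ, an asymmetry index, the coefficient of variation of expression
levels, and the sextile persistence of crosstalk rankings under
transcriptional heterogeneity. Lognormal transcription-rate ensembles,
binding-heterogeneity scenarios over the four CLASH interaction classes
(`kmer`, `seed-nc`, `noseed-9nt`, `noseed`), a heavy-tailed synthetic
interactome generator, and two topology null models (uniform rewiring,
degree-preserving edge swaps) complete the pipeline.

## Worked example

```r
library(ceRNAcross)

# CLASH-like synthetic interactome: heavy-tailed degrees, 77% seed-nc edges
net <- subnetwork_by_modes(generate_network(300, 60, 1200, seed = 42),
                           binding_modes())

# one transcriptional-heterogeneity realization, high binding heterogeneity
p <- kinetic_params(net,
  b    = sample_transcription_rates(length(net$rna_ids), 8, 0.4, seed = 1),
  beta = sample_transcription_rates(60, 30, 0.4, seed = 2),
  bh   = bh_scenario("high"))

fit <- crosstalk_fit(net, p)
summary(fit)
#> Steady-state ceRNA crosstalk fit
#>   279 RNAs, 60 miRNAs, 1200 edges (BH: high)
#>   free RNA fraction 0.015, free miRNA fraction 0.769
#>   mean chi (i != j) 9.562e-05, max chi 2.573e-02, mean chi_ii 0.016
#>   selectivity: S_in 0.0216, S_out 0.0393
#>   locality rho 0.0404, asymmetry 0.514, expression CV 2.12
```

At this miRNA transcription rate (β̄ = 30 molecules/h) the network sits deep
in the repressed side of the susceptible regime: only 1.5% of the
unrepressed RNA pool remains free, the typical pairwise susceptibility
(9.6×10⁻⁵) is ~270-fold weaker than the strongest one (2.6×10⁻²), crosstalk
correlates weakly with the local co-regulation structure (ρ ≈ 0.04), and
pair interactions are strongly directional (asymmetry ≈ 0.5). Ensemble
sweeps over β̄ (`sweep_beta()`) recover the characteristic interior peak of
crosstalk at intermediate miRNA availability.

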