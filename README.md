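# StarrCRE

Locus-level functional annotation of androgen receptor (AR) enhancers for
regulatory genomics of prostate cancer. Most AR binding sites (ARBS) are
not functional enhancers: descriptive marks such as H3K27ac call active
enhancers with a high false-positive rate, and only a reporter assay
resolves, locus by locus, which ARBS actually drive androgen-responsive
transcription. StarrCRE implements the quantitative core of such an
analysis for people working with STARR-seq/MPRA screens of cis-regulatory
elements (CREs), chromatin-loop catalogs, single-cell co-accessibility
scores, and DNA-binding-factor occupancy panels.

## What it computes

**Three-class enhancer calling.** STARR-seq counts (plasmid input, RNA
under vehicle EtOH and androgen DHT) are normalized by median-of-ratios
size factors and tested region-wise with a negative-binomial Wald test
(var = μ + αμ²). Classes follow strict decision rules: *inducible* if
DHT/EtOH LFC > 1 at BH-adjusted p < 0.05; *constitutive* if
plasmid-normalized LFC > 1 in both conditions with DHT/EtOH LFC < 1;
*inactive* if plasmid-normalized LFC < 1 in both; *ambiguous* otherwise.

**CRE network statistics.** Chromatin loops (BEDPE) are mapped to typed
nodes (enhancer classes, DEG promoters via TSS ± 5 kb windows, untested
ARBS). Between classes U and V the interaction frequency is

    IF(U,V) = E_obs / (D · E_max),   D = 2E/(V(V+1)),
    E_max = V(V+1)/2 (within class) or V·U (between classes),

with degree/betweenness centrality on the largest connected component.

**DeltaCon graph perturbation.** Condition-specific co-accessibility
graphs (edges at score > 0.1) are compared through affinity matrices
S = (I + ε²D − εA)⁻¹, ε = 1/(1 + max degree), the root-Euclidean
distance d = √Σ(√s₁ᵢⱼ − √s₂ᵢⱼ)², and a per-node impact w (the row-restricted
distance for nodes with an altered incident edge, 0 otherwise).

**Occupancy ensemble classifier.** Per-factor ChIP-style scores are
normalized by an SES cutoff (maximal ECDF gap versus control) and a
sigmoid anchored at occupancy(cutoff) = 0.1, occupancy(median above
cutoff) = 0.5; the region feature is the max over a 750-bp window. A
bagged multinomial LASSO (many small glmnet fits on ≤ 50 samples × 5
features, aggregate weight = mean over estimators that sampled the
factor) predicts the class, and binding energies (weight × mean class
occupancy) rank the predictive factors.

A first-class synthetic-data module generates all of these inputs with
planted classes, hub enrichment, co-accessibility gains and informative
occupancy factors, so the whole pipeline is testable end to end.

## Worked example

```r
library(StarrCRE)
cfg <- pipelineConfig(
  simulation = list(nClinical = 500, nAreOnly = 50, nPositiveCtrl = 20,
                    nFactors = 30L, informativeFactors = 3L),
  ensemble   = list(nEstimators = 500, nNonInducible = 200),
  seed = 42, logLevel = "quiet")
report <- runPipeline(cfg)
print(report)
```

```
StarrCRE run report (v0.99.0, config 1b91ad31ec65)
Enhancer classes (clinical regions):
        class count percent
    inducible    35     7.0
 constitutive    56    11.2
     inactive   409    81.8
    ambiguous     0     0.0
CRE network: 710 nodes, 873 edges, 101 components
DeltaCon d = 5.905
Classifier accuracy: 0.759
```

Reading the report: of 500 simulated clinical ARBS, 7.0% were called
inducible, 11.2% constitutive and 81.8% inactive — matching the planted
proportions, which default to the fractions observed in the clinical
screen (6.9/11.2/81.9% of 4139 regions). The loop-derived network holds
the typed regions plus DEG promoters; `DeltaCon d` quantifies how much
the co-accessibility graph moved under androgen, and the classifier
accuracy is measured on the held-out 20% split. Individual stages are
available as plain functions (`classifyEnhancers()`,
`interactionFrequency()`, `deltaCon()`, `fitBaggedMultinomialLasso()`,
`bindingEnergy()`, ...) on objects you bring yourself; `runPipeline()`
only wires them together. A shell entry point is provided at
`inst/scripts/run_pipeline.R`.

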