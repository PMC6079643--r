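# xylemnet

Co-expression network analysis for high-spatial-resolution wood-development
expression series — and for anyone who needs a tested, scriptable version of
the MI/CLR co-expression workflow with planted-truth validation.

Wood (secondary xylem) forms through a spatial succession of developmental
stages: cambial division, cell expansion, secondary cell wall (SCW)
deposition, programmed cell death, maturation. Tangential cryosectioning
turns that succession into a sampled axis — each pooled section series of a
tree is an ordered set of transcriptome snapshots — and co-expression
structure along the axis identifies stage-specific gene programs and
candidate regulators (e.g. which transcription factors sit in the network
neighbourhood of the SCW cellulose synthases, and whether those
neighbourhoods are conserved between species). `xylemnet` implements the
full path from a raw gene × sample count matrix to those answers, plus a
negative binomial simulator that generates series with known ground truth so
every stage is testable offline.

## The core computations

* **Variance stabilisation**: median-of-ratios size factors, then the closed
  form `t(n) = (2/ln 2) · asinh √(α n / f_s)` for negative binomial counts
  (variance `μ + αμ²`), log2-like for large counts; expression filter
  "VST > 3 in ≥ 2 samples per tree in ≥ 2 trees"; flank-mean imputation of
  failed samples.
* **Network inference**: pairwise mutual information (equal-frequency,
  equal-width or order-3 B-spline binning), CLR background correction
  `z_i(j) = max(0, (MI_ij − μ_i)/σ_i)` combined as `√(z_i² + z_j²)`,
  scale-freeness threshold scan (log-binned degree distribution, least
  squares on `ln P(k) = a − γ ln k`), signed edges via Pearson correlation,
  largest connected sub-network.
* **Topology**: degree, betweenness, farness/closeness, average neighbour
  degree, with deterministic rank orders.
* **Clustering & domains**: variance filter (σ > 1), Ward clustering
  (correlation distance for genes, Euclidean for samples), k-cluster cut,
  per-gene scaling, and the "within 4% of the gene's maximum" expression
  domain rule.
* **Enrichment**: one-sided Fisher/hypergeometric tests with BH FDR, per
  cluster and per sample domain.
* **Comparative regulomics**: seed neighbourhoods, one-step expansion, TF
  subsetting, and a cross-species neighbourhood-conservation test through an
  ortholog map (hypergeometric overlap; verdict conserved / diverged /
  untestable).

## Worked example

The `analysis/` directory holds the study as numbered drivers
(`01_simulate.R` … `06_comparative.R`); each writes its tables under
`results/`. Running them in order on the default synthetic study prints,
among other things:

```
expressed genes: 600 of 600
scale-freeness scan: best threshold 5.0 (R^2 = 0.921)
network at Z >= 5: 245 edges (5 negative)
variance filter (> 1): 446 of 600 genes kept
cluster recovery vs planted labels: ARI = 1.000
planted module edges at Z >= 5: precision 0.93, recall 0.89
planted diverged seed recovered exactly: TRUE
```

Reading: on a 600-gene series (3 trees × 14–18 sections) the scan picks the
Z ≥ 5 preset on its own; the 446 variance-filtered genes cluster back into
the six planted developmental programs perfectly (adjusted Rand index 1.0);
and on the two-species study the conservation test flags exactly the seed
whose regulon was rewired in species B — its neighbourhood overlap drops to
0/8 (hypergeometric p = 1) while conserved seeds sit at 7/7–8/8 with
p ≤ 10⁻¹². A gene's "expression domain" (samples within 4% of its maximum)
localises it on the developmental axis, and the per-sample enrichment of
planted gene sets annotates the gradient the way stage-specific GO terms
annotate a real series.

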