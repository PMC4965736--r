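# noduleCBIR

Content-based image retrieval (CBIR) for pulmonary nodules on CT, for
medical-imaging researchers building or studying similarity-based
decision support. Given segmented lesion volumes with boundary
annotations, the package extracts a 36-attribute volumetric texture
vector (nine second-order statistics of 3D gray-level co-occurrence
matrices in four orientations), a 12-attribute margin-sharpness vector
(statistics of intensities sampled along boundary-normal lines, clipped
by a lung mask), z-scores the attributes, and ranks stored nodules by
the weighted Euclidean distance

d(x⃗, y⃗) = √( w₁(x₁ − y₁)² + … + w_a(x_a − y_a)² ),  wᶠ ≥ 0, Σ wᶠ = 1.

Its core is an automatic attribute-weighting procedure: two stages
alternate cyclically. The *evaluation stage* scores the current weights
by leave-one-out retrieval, mapping each retrieved nodule's malignancy
rating to a relevance reward s ∈ {4, 2, 0} and accumulating the
discounted gain v = Σᵢ γⁱ sᵢ, so early ranks dominate. The *training
stage* retrieves each training nodule's n nearest neighbors and sets
each attribute's current weight to the inverse standard deviation (ISD)
of its values among those neighbors — locally homogeneous attributes are
good similarity indicators — then folds the result into the weight
memory, W\* = W + α (W_current − W). The best-scoring weights are kept;
the cycle stops after a patience of non-improving evaluations.
Reference parameters: n = 15, α = 0.3, γ = 0.8.

Malignancy ratings follow the LIDC-IDRI 1–5 scale; rating 3 is
discarded, 1–2 count as benign and 4–5 as malignant for evaluation
(interpolated precision at recall 25/50/75 % and Precision(n)).

## Worked example

Extract both attribute vectors from a synthetic nodule phantom, then
learn weights on the seeded benchmark and compare retrieval quality on
the held-out validation database:

```r
library(noduleCBIR)

ph <- generatePhantom(seed = 1)                  # 40x40x7 voxel lesion
gv <- quantizeVolume(ph$volume, ph$mask, levels = 64)
ta  <- textureVector(gv)                         # 36 texture attributes
msa <- marginVector(ph$volume, ph$contours)      # 12 margin attributes
inv <- concatVectors(ta, msa)                    # 48-attribute vector
round(msa[c("diffEnds", "sampleVariance", "skewness")], 3)
#>       diffEnds sampleVariance       skewness
#>         92.000        363.213         -0.105

bm  <- generateBenchmark(seed = 1)   # 4 classes x 20/20/10, 8 attributes
cfg <- trainingConfig(n = 15, alpha = 0.3, gamma = 0.8, patience = 20)
run <- runCycle(trainTable(bm$split), evalTable(bm$split), cfg)
round(run$WBest, 3)
#>   inf01   inf02 noise01 noise02 noise03 noise04 noise05 noise06
#>   0.178   0.193   0.096   0.101   0.083   0.121   0.130   0.097

vd <- validTable(bm$split)
evaluationReport(vd, rep(1/8, 8), n = 15)    # uniform weights (plain ED)
#>       group recall25 recall50 recall75 precisionAtN
#> 1    benign    0.869    0.775    0.661         0.70
#> 2 malignant    0.880    0.790    0.659         0.72
evaluationReport(vd, run$WBest, n = 15)      # learned weights
#>       group recall25 recall50 recall75 precisionAtN
#> 1    benign    0.900    0.840    0.782        0.777
#> 2 malignant    0.933    0.865    0.763        0.787
```

The two informative attributes of the benchmark end up with roughly
twice the weight of the noise attributes, and the learned weights
improve precision at every recall level on data the learner never saw.

A command-line front end wrapping the same functions is installed at
`inst/cli/nodule-cbir.R` with subcommands `simulate`, `extract`,
`normalize`, `split`, `learn`, `retrieve` and `evaluate`; see the
script header for usage.

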