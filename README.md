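# tsnet — network-integrated classification of clinical expression time series

Short clinical gene-expression time courses (a few dozen patients, tens of
genes, 5–7 visits) carry signal about how a patient will respond to a therapy
— for example whether a multiple-sclerosis patient responds to interferon-beta
— but they are noisy, tiny by machine-learning standards, and the genes that
move together are often functionally related, so single-gene markers are
redundant and unstable. `tsnet` classifies such cohorts by integrating a
protein–protein interaction (PPI) network into a temporal-pattern pipeline:

1. **Discretization.** Each gene trajectory is converted into qualitative
   states 1..Q by a hidden Markov model whose per-state emission density is a
   Gaussian mixture with one component per gene,
   b_j(x) = Σ_i w_ji N(x; μ_ji, σ_ji). The model is initialized from an
   equal-frequency binning of the pooled values, trained by Baum–Welch over
   all (patient, gene) sequences, and decoded with Viterbi. Classical
   threshold discretizers (average, mid-range, max−X%max, top X%,
   equal-frequency) are included as baselines.
2. **Temporal biclustering.** From each patient's gene-state matrix, all
   *maximal* biclusters B(G, J(T, S)) — a gene set G sharing an identical
   state profile S over a contiguous time window T — are enumerated by
   sorting time-stamped suffix strings with MSD radix sort and scanning
   longest-common-prefix runs; a brute-force enumerator verifies the result
   on small instances.
3. **Network weighting.** Each bicluster is scored by how densely its genes
   interconnect in the PPI network: for every member gene, the hypergeometric
   upper-tail probability of its edge count into the bicluster given its
   degree; the bicluster score (PPIScore) averages 1 − p over members, and
   per-patient scores are normalized to weights summing to 1.
4. **Similarity kernel.** Bicluster pairs are compared with a time-stamped
   Jaccard index |G₁∩G₂|·|J₁∩J₂| / (|B₁|+|B₂|−|B₁∩B₂|); patients are compared
   with PPISim, a score-weighted symmetrized best-match over their bicluster
   sets, which satisfies PPISim(A,A)=1 and symmetry.
5. **Classification.** A KNN-gated soft-margin SVM: the K most similar
   training patients vote first — a unanimous neighborhood decides directly —
   otherwise a linear SVM with the PPISim kernel is solved (SMO on the dual,
   kernel projected to its nearest PSD matrix) on the neighborhood and
   applied to the test patient. A harness provides 10×4-fold stratified
   cross-validation, a network-ablation comparison (PPI weights vs uniform),
   and early-stage evaluation on the first n visits.

A synthetic-data module generates cohorts with planted gene modules,
class-specific state programs, decoy modules (expression-coherent but
unconnected in the network), and a stochastic-block interaction network, so
the whole pipeline is testable without any external data.

## Worked example

```r
library(tsnet)

sim <- generateDataset(nPos = 8, nNeg = 6, nGenes = 20, T = 6, Q = 3,
                       noiseSd = 0.25, missingRate = 0.05,
                       nModules = 2, decoyModules = 1, moduleSize = 4, seed = 42)
ds  <- imputeMissing(normalizeExpression(sim$dataset))
fit <- hmmDiscretize(ds, Q = 3)
fit$model
#> HmmGmmModel: Q = 3 states, 20 mixture components (genes)
#>   EM iterations: 24, final logLik -2089.9756

profiles <- buildProfiles(fit$states, sim$network, ml = 2, mo = 2)
profiles[["P001"]]
#> PatientProfile 'P001': 25 biclusters
profileBiclusters(profiles[["P001"]])[[1]]
#> Bicluster: 6 genes, window [1, 2], profile {1,1}, score 0.1252

kern <- similarityMatrix(profiles)
classDistanceRatio(kern, patientLabels(ds))
#> [1] 4.513799

report <- crossValidate(sim$dataset, sim$network, tsnetConfig(reps = 2), seed = 1)
report
#> CvReport: 2 repetitions x 4-fold cross-validation
#>     metric mean sd
#>   accuracy    1  0
#>  precision    1  0
#>     recall    1  0
#>  f_measure    1  0
```

The EM trace shows the mixture HMM converging on the pooled trajectories;
patient P001's profile holds 25 maximal biclusters, the first spanning 6
genes over visits 1–2 with a modest network score. The class-distance ratio
D ≈ 4.5 says within-class patients are 4.5× more similar than cross-class
patients under the PPISim kernel, and the planted two-class structure is
recovered perfectly by the cross-validated classifier.

## Command line

A thin wrapper over the same functions is installed under `exec/`:

```sh
Rscript exec/tsnet.R simulate --preset baranzini-like --seed 7 --out sim/
Rscript exec/tsnet.R classify --expression sim/expression.tsv \
    --labels sim/labels.tsv --network sim/network.tsv --K 7 --C 1 --out cv/
```

Subcommands: `simulate`, `preprocess`, `discretize`, `bicluster`, `score`,
`similarity`, `classify`, `run`; every flag overrides the YAML config
(`--config`).

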