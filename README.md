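# spmlmi

Structural-perturbation link prediction for lncRNA–miRNA bilayer networks.

## What problem this solves, and for whom

Experimentally validated lncRNA–miRNA interactions are scarce relative to
the number of plausible pairs, and lncRNA sequences are too poorly
conserved for sequence-based target prediction to work the way it does for
miRNA–mRNA pairs. Under the competing-endogenous-RNA (ceRNA) view,
co-expressed lncRNAs tend to share miRNA partners — so expression
similarity carries predictive signal about interactions. This package is
for computational biologists who have (i) expression profiles for lncRNAs
and miRNAs across tissues/cell lines and (ii) a catalogue of known
interactions, and who want a ranked list of candidate novel interactions
plus an honest measure of how predictable their network actually is.

## The method

Three layers are integrated into one bilayer adjacency matrix over
`N = n + m` nodes (lncRNAs first):

```
A = [ LS    LM ]      LS: n x n lncRNA Pearson-similarity network
    [ LM'   MS ]      MS: m x m miRNA Pearson-similarity network
                      LM: n x m binary known-interaction matrix
```

**Structural perturbation.** Remove a random 10% of the links of each kind
(similarity links and interaction links separately), giving `A = A_R + ΔA`.
Eigendecompose `A_R = Σ_k λ_k x_k x_kᵀ`, correct each eigenvalue to first
order with eigenvectors held fixed,

```
Δλ_k = x_kᵀ ΔA x_k / (x_kᵀ x_k),      Ã = Σ_k (λ_k + Δλ_k) x_k x_kᵀ,
```

and average `Ã` over `t = 8` independent draws. Entries of the averaged
matrix score node pairs: unobserved interaction-block entries with high
scores are the predicted interactions. Degenerate eigenvalues are handled
by diagonalizing `ΔA` within each degenerate eigenspace (see the methods
vignette).

The same machinery yields the **structural-consistency index** `σ_c` — the
fraction of deliberately removed links recovered in the top-L scored
non-links — which quantifies how intrinsically predictable a network's
links are, and a **k-fold cross-validation** harness (reset 1/k of the
known interactions to unknown, refit, rank, ROC/AUC with tie-aware
Mann–Whitney AUC).

A group-structured synthetic generator (`simulate_lmi_data()`) emulates
the statistical shape of the public catalogues at desk scale, so the whole
pipeline runs and is tested without any downloads.

## Worked example

```r
library(spmlmi)

sim <- simulate_lmi_data(seed = 1)      # 120 lncRNAs x 40 miRNAs, 24 conditions
ls  <- expression_similarity(standardize_expression(sim$lnc_expr))
ms  <- expression_similarity(standardize_expression(sim$mi_expr))
bn  <- bilayer_network(ls, ms, sim$interactions)
bn
#> lncRNA-miRNA bilayer network: 160 nodes (120 lncRNAs + 40 miRNAs)
#>   interaction links: 785   similarity links: 7140 (lnc) + 780 (mi)

fit <- spmlmi(bn, t = 8, fraction = 0.1, seed = 42)
head(predict(fit), 5)
#>    lnc_id   mi_id     score rank
#> 1 LNC0051 MIR0013 0.3581524    1
#> 2 LNC0111 MIR0035 0.3442740    2
#> 3 LNC0068 MIR0023 0.3411954    3
#> 4 LNC0052 MIR0016 0.3378313    4
#> 5 LNC0039 MIR0016 0.3363618    5

structural_consistency(bn, fraction = 0.1, n_reps = 10, seed = 7)
#> Structural consistency: 0.3882 +/- 0.0094 (10 reps, 10% removal)

run_cv(bn, k = 5, t = 8, n_repeats = 10, seed = 7)
#> 5-fold cross-validation, 10 repeat(s), t = 8, fraction = 0.1
#>   AUC = 0.8889 +/- 0.0117
#>   top-1/k TPR = 0.9006 +/- 0.0193
```

The top-ranked pairs are unobserved entries whose scores the perturbed
spectrum pushes highest — here they fall in matched co-expression groups,
as the ceRNA premise predicts. `σ_c ≈ 0.39` says that about 39% of a
randomly removed 10% of links are recovered in the top slots, far above
the ~1% chance level; AUC ≈ 0.89 with top-1/k TPR ≈ 0.90 places the
synthetic regime close to the performance reported for real interaction
catalogues.

`predict(fit, query = "LNC0051")` restricts the ranking to one node's
candidates (the typical "which miRNAs should I test against this lncRNA"
question).

## Command line

A thin CLI over the same functions lives at `inst/cli/spmlmi.R`
(subcommands `simulate`, `build`, `consistency`, `predict`, `cv`; YAML
config via `--config`, flag > config > default). Example:

```sh
Rscript inst/cli/spmlmi.R simulate --out-dir data --seed 1
Rscript inst/cli/spmlmi.R build --lnc-expr data/lnc_expr.tsv \
    --mi-expr data/mi_expr.tsv --interactions data/interactions.tsv --out net
Rscript inst/cli/spmlmi.R cv --net net --k 5 --t 8 --repeats 10 --seed 42 --out cv.tsv
```

Every run writes a JSON manifest (command line, resolved config, seed,
package version, input checksums) next to its outputs.

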