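# pairbind

Sequence-based protein–protein binding-affinity regression and alanine-scan
interface mapping, in R.

Identifying which residues drive a protein–protein interaction normally
requires a solved complex structure. `pairbind` implements the
sequence-only alternative: learn a binding-affinity regressor from paired
chain sequences, then locate putative interface residues by *in silico*
alanine scanning — systematically substituting residues (singly or in
contiguous patches) with alanine and ranking positions by the predicted
drop in binding affinity. It is aimed at structural bioinformaticians who
want a fast, structure-free prior on interface location, and at method
developers who need a fully self-contained, oracle-checked test bed for
affinity-based hotspot scanning.

## The model

**Labels.** Measured dissociation constants are converted to a free-energy
score (kcal/mol) with T = 298 K and R = 1.9872 cal mol⁻¹ K⁻¹:

    score = | R·T·ln(K_D) | / 1000

so a 1 M binder scores 0 and a nanomolar binder ≈ 12.3 kcal/mol. The
positive-magnitude convention matches the model's rectified output and the
5–15 kcal/mol range typical of measured complexes.

**Regressor.** A Siamese architecture: both chains pass through one
weight-shared per-residue encoder producing an L×d embedding matrix; each
matrix is max-pooled into a d-vector; the two vectors are fused by a
Hadamard (elementwise) product — making the prediction invariant to chain
order — and a regression head of three (dropout, linear) stages with a
final ReLU maps the fused vector to a non-negative affinity score.
Training is mini-batch AdamW under a selectable loss (squared error,
absolute error, Huber), fully seeded. The encoder is pluggable: a tiny
trainable position-aware encoder for desk-scale work, an adapter for
externally precomputed per-residue embeddings (e.g. from a large protein
language model run offline), and a frozen bidirectional-LSTM baseline with
overlapping-chunk inference (100-residue chunks, 50-residue stride,
averaged over all chunk pairs).

**Scanning and evaluation.** For a pair of chains, every window of 1, 2, 5
or 10 consecutive residues is replaced by alanine; per-residue
ΔΔG = score(wild) − score(variant), with patch>1 windows attributed to
residues by the maximum over covering windows. Ground-truth interfaces are
extracted from dimer structures as residues with any heavy atom within
6.5 Å of the partner chain. A ranking is judged by the *N*-factor metric:
with *n* true interface residues, the top k = N·n ranked positions are
examined and success = 100·hits/n.

## Worked example

Everything below runs offline on generated data: a synthetic 40+40-residue
dimer with five designated interface positions whose energetic weights
(1–3 kcal/mol) define the affinity labels, and a matching toy structure in
which exactly those positions sit within the 6.5 Å cutoff.

```r
library(pairbind)

spec <- synthetic_complex_spec(seed = 42)
ds   <- make_affinity_dataset(spec, n_pairs = 500)
fit  <- affinity_model(ds, embed_dim = 128, hidden = c(64, 32),
                       epochs = 100, lr = 2e-3, dropout = 0, seed = 42)
fit
#> <affinity_model: encoder 'tiny' (d=128, trainable), loss=mse, 100 epochs>
#>   train: 350 pairs, final mse 0.0641, MAE 0.1942 kcal/mol
#>   val:   150 pairs, final mse 0.1219, MAE 0.2812 kcal/mol

scores  <- score_scan(fit, spec$seq_a, spec$seq_b, patch_sizes = 1)
ranking <- rank_residues(scores)
head(ranking, 5)
#>   chain position patch_size      ddG
#> 1     A       38          1 2.575404
#> 2     B       11          1 2.179214
#> 3     A        2          1 2.127688
#> 4     B       38          1 1.551985
#> 5     A       26          1 1.374907

pdb <- tempfile(fileext = ".pdb")
make_toy_pdb(spec, pdb)
truth <- extract_interface(read_complex(pdb, complex_id = "SYN1"), cutoff = 6.5)
truth
#> <interface_set SYN1 @ 6.5 A: chain A: 3 residues, chain B: 2 residues (n = 5)>

n_factor_success(ranking, truth, N = 3, complex_id = "SYN1")
#> <N-factor 3 (SYN1): n=5, k=15, hits=5, success 100.0%>
```

The validation MAE (0.28 kcal/mol) sits clearly below the label spread
(SD ≈ 0.5 kcal/mol on the validation split), and the scan ranks four true
interface positions in its top five: the planted interface (A{2,26,38}, B{11,37}) is fully
recovered within the top 15 (N = 3) ranks. `recovery_experiment()` wraps
this whole pipeline in one call.

Real SKEMPI-style tables are prepared with
`build_dataset(read_skempi_table("skempi.csv"), read_chain_sequences(...))`,
which filters records lacking affinity data, verifies every mutation code
against the chain sequence, deduplicates unordered pairs, and performs the
seeded 70/30 split; `corpus_filter()` applies the evaluation-corpus rules
(heterodimers only, ≤ 2 chains, ≤ 500 residues, leakage exclusion list).
A thin command-line wrapper lives in `inst/scripts/pairbind.R`.

## Scope

The package regresses absolute affinity scores (not mutant-minus-wild
ΔΔG labels), handles two-chain complexes only, reads PDB (not mmCIF),
and performs no masked-language pretraining; large protein language
models enter only through the precomputed-embedding adapter.
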