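# scdblcall

Standalone maximum-likelihood doublet detection for single-cell DNA
sequencing (scDNA-seq) read counts.

## The problem

Droplet and well-based scDNA-seq platforms sometimes capture two cells under
one barcode. These *doublets* corrupt downstream analyses: a **neotypic**
doublet (two cells of unrelated clones) looks like a novel genotype and
breaks clone identification and phylogeny inference, while **nested**
doublets (one cell's mutations a subset of the other's) and **selflets**
(two cells of the same clone) bias clonal abundances. `scdblcall` flags
doublets from nothing but the two droplet-by-locus count matrices a variant
caller already produces — total reads `C` and variant reads `V` — so any
genotyping or tree-building method can run on clean singlets afterwards.

## The model in brief

A diploid singlet can only have latent VAF x ∈ {0, ½, 1}; a doublet carries
four allele copies, so x ∈ {0, ¼, ½, ¾, 1}, and allelic dropout (each copy
lost with probability β) stretches the observable doublet support to
{0, ¼, ⅓, ½, ⅔, ¾, 1}. Per droplet–locus, the read model is a beta-binomial:
copy errors map the template fraction y to p = α_fp + (1 − α_fp − α_fn)·y,
the read-pool fraction is π ~ Beta(p·s, (1−p)·s) with precision s, and
v | c, π ~ Binomial(c, π). Marginalizing genotypes (locus priors μ_wt, μ_het,
μ_hom) and dropout gives the per-entry log-likelihood ratio

    Ω_ij = log P(c_ij, v_ij | doublet) − log P(c_ij, v_ij | singlet)

and, because the log-posterior is linear in the doublet indicators, the
exact maximum a posteriori call is closed-form:

    droplet i is a doublet  ⇔  Σ_j Ω_ij + log(δ / (1 − δ)) > 0,

with δ the doublet prior from the cell-loading rate. μ, α_fp, α_fn and s can
all be estimated from the counts (`estimate_parameters()`); δ can be
grid-searched (`estimate_delta()`) or supplied. A truth-labelled simulator
(`simulate_experiment()`) generates clonal genotypes with SNVs and optional
copy-number aberrations, and `score_calls()` reports precision/recall/F1
overall and per doublet type.

## Worked example

```r
library(scdblcall)

cfg <- sim_config(m = 50, n_droplets = 500, delta = 0.2, coverage = 50,
                  beta = 0.05, seed = 1)
sim <- simulate_experiment(cfg)          # truth-labelled counts

fit <- estimate_parameters(sim$counts, beta = 0.05)
fit$err
#> error_model: beta=0.05 alpha_fp=0.0151692 alpha_fn=0.0318966 s=10.8967 delta=0.14

res   <- omega_matrix(sim$counts, fit$priors, fit$err)
calls <- classify(res)
head(calls, 4)
#>   droplet_id      score    posterior z    call
#> 1      d0001  -4.232545 1.430772e-02 0 singlet
#> 2      d0002 -15.652799 1.592486e-07 0 singlet
#> 3      d0003  -1.202827 2.309726e-01 0 singlet
#> 4      d0004  -1.865790 1.340297e-01 0 singlet

score_calls(sim$truth, calls)[, c("precision", "recall", "f1")]
#>   precision recall   f1
#> 1     0.972  0.651 0.78
```

Reading the output: `score` is the droplet's log posterior odds of being a
doublet (natural log), `posterior` its logistic transform; droplet `d0002`
is a near-certain singlet, `d0003` an ambiguous one that stays below the
calling threshold. With the parameters estimated from the counts alone
(note the grid-estimated δ = 0.14 against a true 0.2), 71 of 500 droplets
are called doublets, recovering 65% of the true doublets at 97% precision.

## Command line

A thin executable wraps the same functions:

```sh
scdblcall simulate --config sim.yaml --outdir out/
scdblcall call --alt out/alt.tsv --total out/total.tsv \
               --delta 0.2 --beta 0.05 --out out/calls.tsv
scdblcall evaluate --truth out/truth.tsv --calls out/calls.tsv \
                   --out out/metrics.json
```

Count TSVs have droplet identifiers in the first column and locus
identifiers in the header; rows and columns are matched by label, so
differently ordered exports are fine.

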