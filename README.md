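# clonemix

Identifies vaccine-specific B-cell receptor (BCR) clones from CDR3
repertoire sequencing of a vaccinated cohort sampled before and after
vaccination. It is aimed at immunologists and statisticians analysing
repertoire vaccine studies who want a model-based alternative to ad-hoc
abundance/sharing thresholds.

## The model

Unique CDR3 sequences are first clustered into clones (greedy same-length
clustering at >85% nucleotide / >90% amino-acid identity), giving a count
tensor `x[i, s, t]` over clones, individuals and time points. Each clone
carries a latent class `γᵢ ∈ {bg, ns, vs}` — background, non-specific
responder, vaccine-specific — with mixture weights `Γ`. Conditional on
class, presence in individual `s` is `z_is ~ Bernoulli(p_class)` (one `p`
shared by `bg` and `ns`, a free `p_vs` capturing convergent response), and
counts follow a two-regime abundance model: a *quiet* regime (`bg` always;
`vs` pre-vaccination) and an *active* regime (`ns` always; `vs`
post-vaccination). Given presence, a sample's count is zero with
escape-sampling probability `1 − q`, and otherwise drawn from a
zero-truncated negative binomial (weight `1 − ω`) or a heavy-tailed
discretized generalized Pareto (weight `ω`). The joint probability
factorizes as

```
p(θ, γ, z, e, x) = p(θ) ∏ᵢ p(γᵢ) ∏ₛ p(z_is | γᵢ) ∏ₜ p(e_ist | γᵢ, z_is, t) p(x_ist | e_ist, θ)
```

and is maximized by Expectation-Maximisation with a biologically anchored
initialization that fixes each class to its meaning (no label switching,
no post-hoc relabelling). The time-switch of the `vs` class plus its free
sharing probability is what separates vaccine response from other
expansion. See the vignette (`vignettes/mixture-model-methods.Rmd`) for
the full account.

The package also provides the generative simulator, a quantile
abundance/sharing thresholding baseline, a bootstrap Levenshtein
similarity test with petri-plot edge lists, and evaluation against
enrichment-derived truth sets (antigen-sorted or plasmablast sequences).

## Worked example

Simulate a cohort from the generative model at the reference study
conditions (5 individuals, 5 time points, hepatitis-B-style parameters)
and refit:

```r
library(clonemix)
gen <- default_sim_params()
sim <- sample_dataset(gen, K_target = 20000, S = 5, T = 5, seed = 7)
fit <- fit_mixture(sim$tensor, tol = 1e-3, max_iter = 200)
print(fit)
#> Mixture fit: 20000 clones, 117 EM iterations (converged), log joint -288471.9464
#> Class counts (MAP):
#>    bg    ns    vs
#> 19842    68    90
#> Clonal abundance mixture parameters
#>   Gamma (class proportions): bg=0.9907, ns=0.004818, vs=0.004461
#>   p (presence): bgns=0.314, vs=0.9865
#>   q (sampling | present): Q=0.5008, A=0.5193
#>   omega (high-abundance | observed): Q=0.004801, A=0.2522
#>   regime Q: ZTNB(mu=1.006, size=0.7984), dGPD(xi=0.23, sigma=12.87, u=1)
#>   regime A: ZTNB(mu=7.675, size=1.379), dGPD(xi=0.6358, sigma=45.72, u=1)
```

The fitted mixture puts 99.1% of clones in the background class and
recovers the generating parameters: `Γ_bg` (truth 0.992), `p_vs` (0.970)
and `ω_A` (0.277) are each within their Monte-Carlo error, while the
clones labelled `vs` show the vaccine signature directly:

```r
prof <- summarize_profiles(sim$tensor, classify_clones(fit)$label)
subset(prof, label == "vs")
#>    label time mean_rel_abundance mean_sharing
#> 3     vs    0       0.0001289523     2.277778
#> 6     vs    1       0.0016396286     2.644444
#> 9     vs    2       0.0017642954     2.444444
#> 12    vs    3       0.0016038625     2.555556
#> 15    vs    4       0.0018506020     2.655556
```

— a >10-fold jump in mean relative abundance after `t = 0` and sharing
across ~2.5 of 5 individuals, versus 0.79 for background clones.

For real data the entry point is `read_repertoire()` (plain TSV,
AIRR-style TSV or FASTA) followed by `build_clones()`, `fit_mixture()`
and `classify_clones()`; `run_pipeline()` chains the steps and writes all
artifacts, and `inst/cli/clonemix` exposes every step as a shell
subcommand.

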