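# nifhact

Total versus active diazotroph communities from paired *nifH* DNA/RNA
amplicon libraries.

## What problem this solves

Marine nitrogen fixation is carried out by diazotrophs whose *nifH* gene
is the standard survey marker. Sequencing *nifH* from DNA profiles the
**total** community (who is present); sequencing *nifH* mRNA as cDNA
profiles the **active** community (who is transcribing nitrogenase). The
two can disagree sharply — a hyperdominant genus may transcribe modestly
while taxa near the DNA detection limit carry a disproportionate share of
transcription. `nifhact` is for microbial ecologists who have paired
DNA/RNA OTU count tables and qPCR cycle-threshold measurements and want
that disagreement quantified, reproducibly.

The pipeline: repeated-rarefaction normalization of library depths →
alpha diversity (Shannon *H*, Simpson *D*, Pielou *J*, Chao1) with
total-vs-active contrasts → Bray-Curtis / NMDS / beta-dispersion
permutation test → OTU ranking, group frequencies and DNA:RNA
proportionality → qPCR-anchored expression ratios

```
R_bulk  = E ^ dCt,        dCt = mean Ct(DNA) - mean Ct(cDNA)
R_group = R_bulk * f_RNA / f_DNA
```

with `E` the amplification efficiency (`10^(-1/slope)` from a standard
curve) and `f` a group's relative abundance in each library. `R_group` is
undefined when a group never appears in the DNA library (`f_DNA = 0`).
A synthetic-community generator with known per-taxon activity multipliers
provides ground truth for validating every stage.

## Worked example

Simulate a 9-station survey (paired 4746-read libraries, one dominant
filamentous cyanobacterium, rare-but-active and present-but-silent
groups), then fit the whole analysis:

```r
library(nifhact)

spec <- community_spec()               # paper-like default scenario
sim  <- simulate_pads(spec, seed = 1)
tax  <- setNames(spec$taxa$group, spec$taxa$taxon_id)

fit <- pads_activity(sim$dna, sim$rna, taxonomy = tax, qpcr = sim$qpcr,
                     top_n = 8, seed = 1)
summary(fit)
```

```
Alpha-diversity contrasts (active RNA vs total DNA):
 index      t  p_welch     F  p_anova direction mean_DNA mean_RNA
     H  7.062 8.62e-05 49.88 2.69e-06       RNA  0.15120   0.5543
     D  6.640 1.44e-04 44.09 5.69e-06       RNA  0.05020   0.2496
     J  7.328 6.75e-05 53.71 1.70e-06       RNA  0.07622   0.3094
 chao1 -4.914 1.17e-03 24.14 1.56e-04       DNA  7.44400   6.0000

Beta-dispersion: F = 27.51, parametric p = 8.01e-05, permutation p = 0.001 | NMDS stress-1 = 0.00344

Bulk RNA/DNA ratio: mean 0.207, range 0.124 - 0.329

Group expression ratios:
                       group mean_r_group min_r_group max_r_group n_undefined
         Deltaproteobacteria        6.150       2.410      20.500           0
 heterocystous cyanobacteria        3.530       1.490       8.770           0
               Trichodesmium        0.185       0.102       0.301           0
   unicellular cyanobacteria        4.270       2.320       6.670           5
 ...
```

Reading this: the active (RNA) community is significantly more diverse
(Shannon 0.55 vs 0.15, p < 0.001) and more dispersed between stations
(permutation p = 0.001) than the total (DNA) community. The dominant
genus transcribes below the bulk level (mean ratio 0.185 against a bulk
mean of 0.207), while the rare heterocystous group is ~3.5× enriched —
the generator's true multiplier for that group is 3.51. `n_undefined`
counts stations where a group was absent from the DNA library, reported
as `n.d.` rather than a number. `coef(fit)` returns `R_bulk` and the
per-group means; `plot(fit)` draws the ordination, dispersion and
expression panels.

File-based workflows use `run_pipeline()` (YAML config with the paths to
the count, metadata, taxonomy and qPCR files) which writes every stage's
TSV/JSON outputs plus a reproducibility manifest, and
`generate_report()` for a plain-text summary. `write_pads_sim()` emits a
synthetic dataset in exactly that input layout.

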