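# conjscreen

Tools for finding and characterizing plasmid-borne conjugation **exclusion
factors** — recipient-encoded proteins that block the entry of related mobile
elements — from three complementary kinds of evidence:

1. **Transposon-directed insertion sequencing (TraDIS) screens.** A dense Tn5
   insertion library in a plasmid-bearing recipient is mated with a donor; the
   mutants that acquire the mobilized plasmid form the output library. Genes
   whose disruption *enhances* acquisition (exclusion factors) are enriched in
   the output. `conjscreen` simulates the whole experiment (reference,
   library, selection, junction reads) and scores real or simulated reads:
   tag trimming, exact-seed junction mapping, per-gene insertion indices and
   candidate calling.
2. **Mating assays.** Transfer frequencies (transconjugant/donor CFUs),
   exclusion indices (frequency toward an empty recipient divided by the
   frequency toward the tested recipient) and the standard statistical
   treatment: Bartlett's test, one-way ANOVA and Tukey–Kramer post test on
   log10 frequencies, summarized as a compact letter display.
3. **Comparative genomics.** Homolog-hit filtering (≥45% identity, ≥85%
   coverage), global protein alignment (Needleman–Wunsch/Gotoh, BLOSUM62,
   affine gaps) with percent identity, CD-HIT-style greedy identity
   clustering at 0.90, and identity heatmaps — plus inference of **surface
   exclusion groups** from an sfx × traN exclusion-index matrix.

The intended audience is microbial geneticists analysing conjugation screens
of IncC/IncA-family multidrug-resistance plasmids and their relatives, but
every component is generic.

## The statistics at the core

* **Insertion index** of gene *g* in a library:
  `II_g = (unique insertion sites in g) / (length of g) / (total unique
  sites in the library)`. The score of the screen is the output/input ratio
  `R_g = (II_g^out + pc) / (II_g^in + pc)` with a small pseudocount `pc`;
  genes with `R_g > 5` (an intentionally arbitrary threshold) are candidates.
* **Transfer frequency** `T = transconjugants / donors`; zeros are censored
  at the detection limit `1/donors`. **Exclusion index**
  `EI = T_empty / T_test`; `EI ≈ 1` means no exclusion.
* **Tukey–Kramer**: for groups *i*, *j*,
  `q = |m_i − m_j| / sqrt((MSW/2)(1/n_i + 1/n_j))`, with p-values from the
  studentized range distribution; group letters encode exactly the
  nonsignificance graph at α = 0.05.
* **Surface exclusion groups**: binarize the EI matrix at `EI ≥ 10`; traN
  variants with identical binary exclusion profiles across all sfx variants
  form one group.

## Worked example

Simulate a screen with one planted exclusion gene and score it:

```r
library(conjscreen)

r   <- generate_reference(50, seed = 1)          # chromosome + plasmid
lib <- simulate_insertion_library(r$assembly, 1e4, seed = 501)
mod <- selection_model(base_rate = 0.01,
                       effects = c(gene025 = 20)) # disrupting gene025 boosts
out <- apply_conjugation_selection(lib, mod, r$annotation, seed = 1001)

tag <- "TAAGAGACAG"
rin  <- synthesize_reads(lib, r$assembly, tag, 50, 0, 10, seed = 1501)
rout <- synthesize_reads(out, r$assembly, tag, 50, 0, 10, seed = 2001)
sc   <- run_screen(rin, rout, r$assembly, r$annotation, tag)

sc$candidates[sc$candidates$candidate, c("gene_id", "ratio")]
#>    gene_id    ratio
#> 25 gene025 12.19570
```

Only the planted gene crosses the ratio-5 threshold: its disruption raised
the acquisition probability 20-fold, so its insertions are ~12–17× enriched
(after normalization) in the output library. A neutral gene sits near ratio 1.

The same functions run from the shell via the thin `exec/conjscreen`
dispatcher (`simulate`, `screen`, `mating-stats`, `groups`, `homology`
subcommands).

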