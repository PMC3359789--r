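# labmotif

Network-motif detection for **samples of directed networks that share one set
of pairwise-distinct vertex labels** — the situation of effective connectivity
networks (ECNs) estimated over a fixed EEG electrode montage, where every
network in a study group lives on the same nine labeled electrodes
(F3, Fz, F4, C3, Cz, C4, P3, Pz, P4).

Vertex labels change the motif problem fundamentally. Two subnetworks are
identical **iff they have the same set of directed labeled edges**, so
isomorphism never has to be decided, and each subnetwork can occur **at most
once per network**. Counts in a single network therefore carry no
significance; significance comes from counting across the sample. The
classical z-score-against-rewired-ensembles machinery does not apply — an
analytic null takes its place.

## The method

For a sample 𝒩 = (𝒩₁, …, 𝒩ₙ) of simple digraphs on ν shared labels, with kᵢ
edges in member i:

1. **Enumeration.** For every member, every combination of ν_S vertices is
   examined; each weakly connected *induced* subnetwork is recorded by its
   canonical labeled edge set, and the number of members containing each
   distinct subnetwork is counted.
2. **Null model.** Independent-edge (Erdős–Rényi) digraphs with edge
   probability equal to the sample's normalized mean edge count,

   q = (1 / (n · ν(ν−1))) · Σᵢ kᵢ.

3. **Occurrence probability.** A subnetwork S with η_S edges on ν_S vertices
   (at most η_Smax = ν_S(ν_S−1)) occurs as an induced subnetwork of a null
   network with probability

   P(S) = q^{η_S} · (1−q)^{η_Smax − η_S},

   and its count across the sample is Binomial(n, P(S)).
4. **Test.** One-sided exact binomial upper-tail p-value per subnetwork
   (overrepresentation only), Holm step-down correction over the family of
   all C(ν, ν_S) · W(ν_S) connected labeled patterns of that order
   (W(3) = 54, so 4536 hypotheses for 3-subnetworks on 9 labels), familywise
   level α = 0.05. Subnetworks surviving the correction are the motifs.

## Worked example

```r
library(labmotif)

s <- generate_ecn_like_sample(seed = 42, plant = "C3>Cz;Cz>C3;Cz>C4",
                              penetrance = 1)
fit <- motif_detect(s, size = 3)
fit
```

```
Labeled-network motif detection
  sample:  n = 16 networks on 9 labels
  null:    independent-edge density q = 0.506076
  test:    order 3, alpha = 0.05, Holm family m = 4536 (all-possible)
  result:  927 observed subnetworks, 1 motif

Top 10 subnetworks by p-value:
          subnetwork size eta count mean_count  p_null   p_value    p_holm is_motif
1  C3>Cz;Cz>C3;Cz>C4    3   3    16     1.0000 0.01562 1.253e-29 5.685e-26     TRUE
2  Cz>C4;Cz>F3;F3>Cz    3   3     4     0.2500 0.01562 9.316e-05 4.225e-01    FALSE
...
```

The sample was drawn at the ECN-like density 36.79/72 with the pattern
C3↔Cz, Cz→C4 forced into every member. The fitted null density q ≈ 0.506
gives every 3-vertex pattern occurrence probability ≈ q³(1−q)³ ≈ 1/64; a
count of 16/16 then has binomial tail ≈ 1.3e−29, which survives the Holm
correction over 4536 patterns (adjusted p ≈ 5.7e−26) — the planted pattern is
the only motif. The runner-up, with 4 of 16 occurrences, does not survive
(adjusted p ≈ 0.42).

`summary(fit)` lists only the motifs; `coef(fit)` returns q; `residuals(fit)`
gives Pearson residuals of observed vs expected counts; `simulate(fit)` draws
new samples from the fitted null; `plot(fit)` shows observed against expected
counts. `write_motif_table(fit, "motifs.tsv")` writes the full table.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","labmotif.R",package="labmotif"))')" \
    simulate --seed 42 --plant 'C3>Cz;Cz>C3;Cz>C4' --penetrance 1 --outdir nets/
# ... detect --input nets/ --format edgelist --size 3 --alpha 0.05 --output motifs.tsv
```

Networks are plain-text edge lists (`#labels:` header, one `tail head` per
line) or labeled adjacency CSVs (**row = tail, column = head** — transposing
a matrix reverses every motif).

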