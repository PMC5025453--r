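# mapkcascades

Genome-wide analysis of the plant **MAPK kinase kinase (MAPKKK)** gene
family, built around the *Brachypodium distachyon* family, for
researchers studying MAPK signal-transduction cascades
(MAPKKK → MKK → MPK).  The package turns the steps of such a study into
tested, reusable functions:

* **Subfamily classification** — MEKK / Raf / ZIK calls from the
  kinase-domain signature motifs
  (`GTPEFMAPE(L/V)(Y/F)`, `G(T/S)Px(F/W)MAPEV`, `GTxx(W/Y)MAPE`)
  combined with the subfamily's characteristic domain position, plus
  theoretical MW and pI.
* **Gene structure** — cDNA/UTR/CDS lengths, intron counts, splice-site
  phases (prior CDS bases mod 3), and the intron pattern restricted to
  the kinase-domain codons.
* **Molecular evolution** — global protein alignment (affine-gap
  Needleman–Wunsch), tandem-duplicate classification (identity > 70 %,
  coverage > 70 % of the longer gene, tight linkage), protein-guided
  codon alignment, **Nei–Gojobori (1986)** Ka/Ks with Jukes–Cantor
  correction `d = -¾ ln(1 − 4p/3)`, duplication dating under a
  synonymous clock `T = Ks/(2λ)` with λ = 6.1 × 10⁻⁹ site⁻¹ yr⁻¹, and
  Saitou–Nei neighbor joining.
* **Expression screens** — CV (%), log2 fold change with a
  low-expression floor, a SAM-style permutation test with q-values,
  balanced two-way ANOVA with interaction (BH-adjusted), duplicate-pair
  expression PCC, and isoform fold-change comparison.
* **Circadian detection** — cosine-template correlation
  (`cos 2π(t−φ)/P`, P = 24 h) at a correlation cutoff of 0.8.
* **Promoter scanning** — IUPAC consensus elements (HSE, TCA-element,
  ABRE, motif-IIb, CGTCA/TGACG, circadian) on both strands.
* **Co-expression networks** — Pearson correlation → reciprocal ranks →
  **Mutual Rank** `MR(i,j) = √(rank_i(j)·rank_j(i))`, thresholded edges
  (MR < 1500 by default), and prediction of MAPKKK–MKK–MPK cascade
  triads that share a subcellular localization.
* **Synthetic data** — generators for gene families, duplicate pairs
  with a target Ks, expression compendia with planted differential,
  circadian and co-expression signals, and promoters with planted
  elements — every planted signal recorded in a truth table, so all of
  the above is testable without downloads.

## Worked example

```r
library(mapkcascades)

# simulate a small family and classify it back
fam <- simulate_gene_family(n_genes = 8, seed = 42)
calls <- vapply(seq_along(fam$proteins), function(i) {
  tr <- fam$truth[i, ]
  classify_subfamily(list(sequence = fam$proteins[[i]],
                          kinase_domain = c(tr$domain_start, tr$domain_end)))
}, "")
table(truth = fam$truth$subfamily, call = calls)
#>       call
#> truth  MEKK Raf ZIK
#>   MEKK    4   0   0
#>   Raf     0   3   0
#>   ZIK     0   0   1

# duplicate-pair arithmetic on the shipped pair table
tab <- bd_duplicate_pairs()
r <- tab[tab$locus1 == "BdMAPKKK26" & tab$locus2 == "BdMAPKKK27", ]
sprintf("Ka/Ks = %.6f, T = %.2f Myr", kaks_ratio(r$ka, r$ks),
        divergence_time(r$ks))
#> "Ka/Ks = 0.047996, T = 15.54 Myr"

# synonymous divergence simulation hits its NG86 target
pair <- simulate_duplicate_pair(fam$cds[[1]], target_ks = 0.2, seed = 1)
k <- ng86_kaks(pair$cds_a, pair$cds_b)
sprintf("simulated pair: Ka = %.4f, Ks = %.4f", k$ka, k$ks)
#> "simulated pair: Ka = 0.0000, Ks = 0.1825"

# a planted co-expression triad becomes a predicted cascade
genes <- sprintf("g%02d", 1:20)
sim <- simulate_expression(genes,
                           coexpr = list(triads = list(c("g02","g09","g15")),
                                         triad_cor = 0.95, n_samples = 30),
                           seed = 3)
mr <- mutual_rank(pcc_matrix(sim$values))$mr
edges <- build_network(mr, cutoff = 5)
fams <- setNames(rep("other", 20), genes); fams[c("g02","g09","g15")] <-
  c("MAPKKK", "MKK", "MPK")
locs <- setNames(rep("Cytoplasm", 20), genes)
predict_cascades(edges, fams, locs)
#>   mapkkk mkk mpk localization mr_kkk_kk mr_kk_k
#> 1    g02 g09 g15    Cytoplasm  1.414214       1
```

The classification table shows every simulated gene recovered in its
true subfamily; the Ka/Ks row reproduces the published ratio and clock
date for the youngest tandem pair; the simulated duplicate's NG86 Ks
estimate (0.18) sits at its 0.2 target within sampling error; and the
planted triad surfaces as the single colocalized cascade with both
Mutual-Rank edges at the theoretical minimum.

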