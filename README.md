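# triadminer

Discovery and characterization of LPR1-type multicopper-oxidase (MCO)
ferroxidases from protein sequence, and the analyses that go with the
claim: homology-hit filtering, profile screening, a topological test of
horizontal gene transfer (HGT), and ferroxidase enzyme kinetics.

## The science

LPR1-type ferroxidases oxidize Fe²⁺ at a substrate site formed by an
**acidic triad** — three acidic residues (E269, D370, D462 in Arabidopsis
LPR1 numbering), each embedded in a short conserved context. The triad is
recognizable directly in sequence via three degenerate consensus motifs:

```
M1: [WVI]XP[EA][YAF]X[GA]
M2: N[DTS][AG]XXP[YF]PXG[DE]X(5-10)[VI][ML]XF
M3: NXTX[DEG]XHP
```

(`[..]` residue class, `X` wildcard, `X(m-n)` bounded gap; the underlined
triad residue is the *anchor* class of each motif: `[EA]`, `[DE]`,
`[DEG]`.) A sequence covering at least two of the three motifs, in order,
is *considered* an LPR1-type candidate; triad completeness is reported as
3/3, 2/3, 1/3 or absent.

Around the classifier the package provides:

* **Hit filtering** with the published thresholds — query coverage > 60%,
  e-value ≤ 1e-40, identity > 30% (tblastn mode); alignment length > 175
  residues, coverage > 30% (profile mode).
* **Profile screening**: a position-specific log-odds profile (PSSM) built
  from an alignment with pseudocounts, slid over candidate sequences.
* **Phylogenetics**: p-distance/Poisson distances, deterministic
  neighbor joining, midpoint rooting, seeded column-bootstrap supports,
  and `hgt_consistency()` — is the plant clade monophyletic **and** nested
  inside the bacterial radiation (bacteria not themselves a clade)?
* **Kinetics**: ferrozine absorbance → Fe²⁺ (ε₅₆₀ = 25,400 M⁻¹cm⁻¹),
  oxidation rates, background subtraction, and Michaelis–Menten fitting
  v = V·S/(K_M + S) by nonlinear least squares with Hanes–Woolf
  initialization; plus ICP-MS μg/g → μM medium conversion.
* **Synthetic data**: seeded generators for motif-planted proteins, hit
  tables, HGT tree scenarios, tree-evolved alignments and assay data, each
  with a truth table, so the whole pipeline runs and is tested offline.

## Worked example

```r
library(triadminer)

# 1. classify a protein: the shipped synthetic LPR1-like sequence carries
#    the triad at the documented coordinates
fa <- system.file("extdata", "lpr1_like_synthetic.fasta", package = "triadminer")
classify_collection(fa)[, c("seq_id", "completeness", "label", "anchors", "considered")]
#>                seq_id completeness    label                    anchors considered
#> 1 LPR1_like_synthetic            3 complete M1:269:E;M2:370:D;M3:462:D       TRUE

# 2. fit ferroxidase kinetics on synthetic assay data (true K_M = 1.8 uM)
g <- gen_kinetics(km_uM = 1.8, vmax = 10,
                  S_grid = c(0.5, 1, 2, 5, 10, 25, 50, 100, 200),
                  noise_cv = 0.05, seed = 42)
fit_mm(g$series)
#> <mm_fit> Km = 1.809 uM (SE 0.14), Vmax = 10.08 (SE 0.15), RSS 5.9, converged

# 3. test the HGT topology on a simulated transfer scenario
sc  <- gen_hgt_scenario(seed = 1)             # plant clade grafted into bacteria
msa <- evolve_msa(sc$tree, 500, seed = 2)     # sequences evolved on that tree
run_phylo(msa, sc$labels, n_bootstrap = 100, seed = 3)$clade_test
#> <clade_test> 6 ingroup / 16 outgroup tips: monophyletic=TRUE, nested=TRUE (support 1)

# 4. medium chemistry: 7.3 ug/g Fe in 1% w/v agar
medium_micromolar(7.3, agar_percent_wv = 1, molar_mass_g_mol = 55.845)$uM_2sf
#> [1] 1.3
```

The triad classification says all three motifs were found in order with
their anchors at E269/D370/D462; the kinetic fit recovers the generating
Michaelis constant within its standard error; the clade test confirms the
plant sequences form one clade nested inside the bacterial radiation with
full bootstrap support; and the agar iron content converts to a 1.3 μM
contribution to the growth medium.

See `vignettes/triadminer-methods.Rmd` for the models, conventions and
limitations.

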