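---
title: "Codon usage bias and adaptation to the tRNA pool with codonAdapt"
author: "codonAdapt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias and adaptation to the tRNA pool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonAdapt)
```

## The scientific question

Synonymous codons are not used equally. Two forces shape the choice:
mutational bias (GC pressure) and translational selection — codons read by
abundant tRNAs are translated faster and more accurately, so highly
translated genes accumulate "optimal" codons. `codonAdapt` quantifies this
from three inputs a genome project typically has at hand:

* a CDS FASTA (the coding sequences),
* a tRNAscan-SE gene table (anticodon gene copy numbers, tGCN, as a proxy
  for tRNA abundance),
* a two-condition expression table (per-gene log2 signals and p-values).

It computes the classical per-gene indices — RSCU, CAI, Wright's Nc,
codon-pair score/bias (CPS/CPB), and the tRNA adaptation index (tAI) with
its amino-acid-normalized variant (AAtAI) — and then asks whether the genes
*induced* in the second condition are better adapted to the tRNA pool than
the rest of the genome: the signature of translational selection acting on
a metabolic program, as described for lignocellulose degradation in the
white-rot fungus *Ceriporiopsis subvermispora*.

## The model, index by index

**Codon and codon-pair frequencies.** All counting is over validated coding
sequences: length divisible by 3, pure ACGT, no internal stop; a terminal
stop is stripped and never counted, so stops appear in no frequency, weight
or pair. Frequencies are reported per thousand codons (f(A)) and per
thousand ordered adjacent pairs (f(AB)); pairs never span gene boundaries.

**RSCU.** The count of a codon divided by the mean count over its
synonymous family; values sum to the family size. Families never observed
are flagged, not zero-filled.

**CAI.** Each codon's weight is its frequency relative to the most-used
codon of its family, derived from a reference corpus — by default the
analyzed gene set itself, i.e. genome-wide usage (a custom reference table
is accepted). A gene's CAI is the geometric mean of its codons' weights.
Met/Trp are included (the EMBOSS convention; the Sharp–Li exclusion is a
switch), and zero-frequency codons get a 0.01 floor weight so rare codons
penalize rather than annihilate the score.

**Nc (effective number of codons).** Wright's homozygosity-based statistic:
per synonymous family with usage $n \ge 2$,
$\hat F = (n\sum p^2 - 1)/(n-1)$; with class averages over the 2-, 3-, 4-
and 6-fold families,
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, capped at
61. A missing 3-fold class (Ile unused) is imputed as
$(\bar F_2 + \bar F_4)/2$; if any other class is missing the gene's Nc is
NA. Nc runs from 20 (one codon per amino acid) to 61 (uniform synonymous
usage); lower means stronger bias.

**CPS and CPB.** The codon-pair score corrects observed pair usage for both
codon usage and amino-acid-pair usage:
$$\mathrm{CPS}(AB) = \ln\!\left(\frac{f(AB)}{f(A)\,f(B)}\cdot
\frac{f(X)\,f(Y)}{f(XY)}\right),$$
where X, Y are the amino acids coded by A and B. The per-thousand scalings
cancel, so the package computes the score exactly from raw counts. A gene's
CPB is the arithmetic mean of CPS over its $l-1$ adjacent pairs. Pairs
unobserved in the reference corpus are flagged NA by default; a lenient
mode scores them with a 0.5-count pseudocount. Natural logarithm
throughout.

**tAI and AAtAI.** The absolute adaptiveness of codon $i$ to the tRNA pool
is
$$W_i = \sum_{j=1}^{n_i} (1 - S_{ij})\,\mathrm{tGCN}_{ij}$$
over the anticodons $j$ that recognize it, where $S_{ij} \in [0,1]$ is the
selective constraint of the pairing geometry. The recognition rules and
default constraints follow the reference tAI parameterization: each codon
is read by its Watson–Crick anticodon ($S=0$) plus one wobble isoacceptor —
G34 for codons ending T ($S=0.41$), A34-as-inosine for codons ending C
($S=0.28$) and A ($S=0.9999$), U34 for codons ending G ($S=0.68$); ATG is
read only by CAT (elongator Met), TGG only by CCA (its wobble donor would
Watson–Crick-decode a stop), and under prokaryote mode ATA is read by
lysidine-modified CAT ($S=0.89$). The constraints live in a YAML config
(`inst/extdata/wobble_constraints.yaml`), not in code, because they are a
parameterization, not an identity: the literature defaults are used and
remain overridable (`--s-constraints`).

tAI is the geometric mean over a gene's codons of $w_i = W_i/W_{\max}$;
AAtAI uses ${}^{AA}w_i = W_i/W_{AA\max}$ with $W_{AA\max}$ the best codon
of the same family, so AAtAI measures *within-family* codon choice and
AAtAI $\ge$ tAI always. Codons with $W_i = 0$ (no tRNA serves them) receive
the geometric mean of the non-zero values — a hard zero would annihilate
the geometric mean of any gene containing the codon — and the substitution
is recorded in the `AdaptivenessVector`. A family-normalized variant
$W_i/\sum_{\mathrm{family}} W_j$ (optionally times family size, the
`family_norm_scale` switch) is provided for correlations against RSCU,
where normalizing by the family pool rather than the global maximum is the
relevant scaling.

**Z-values.** Each index is standardized over the whole gene set,
$Z = (x - \mu)/\sigma$ with the population SD ($n$ denominator; at
genome-scale corpora the distinction from $n-1$ is negligible, but the
convention is fixed for reproducibility). Genes with an undefined index are
excluded from that index's moments.

## Expression integration

Expression ratios are recomputed from the log2 signals
($\mathrm{ratio} = 2^{\mathrm{bma} - \mathrm{glu}}$) rather than trusted
from an input column, keeping the pipeline self-consistent. Genes are
classified with a fixed boundary policy (fold threshold $F=2$, significance
$\alpha=0.05$):

* **A** — repressed: ratio $\le 1/F$ and $p < \alpha$;
* **B** — induced: ratio $\ge F$ and $p < \alpha$;
* **C** — unchanged: $p \ge \alpha$ (ties at exactly $\alpha$ fall here);
* **D** — significant but sub-threshold: $p < \alpha$, $1/F <$ ratio $< F$.

Group B is compared against each of A, C, D per index with two-sided
Mann–Whitney tests (exact null at small n without ties, normal
approximation with tie correction otherwise — the `stats::wilcox.test`
contract), and each index is Spearman-correlated with the two signals and
their ratio, overall and within p-value strata (p < 0.001, 0.001–0.05,
≥ 0.05). Spearman is rank-based, so whether signals are correlated on the
log2 or linear scale is immaterial. Raw p-values are reported (no
multiple-testing correction, matching the descriptive use of these tests;
`p.adjust` can be applied downstream). Sidedness is two-sided throughout.

## The synthetic study

The generator (`runSimulate`) emulates the three inputs with known ground
truth so the full pipeline is testable without downloads:

* **tRNA pool** — a eukaryote-like anticodon set (G34 for 2-fold pyrimidine
  families, U34+C34 for purine families, A34/U34/C34 for 4-fold boxes,
  covering every sense codon under the default wobble rules) with copy
  numbers $1 + \mathrm{NegBin}$ (long-tailed, mean ≈ 4 copies, range ~1–20,
  matching the skew of real fungal pools where single anticodons reach 12+
  copies), scattered over scaffolds with intron flags, written as a valid
  tRNAscan-SE file.
* **CDS** — amino acids i.i.d. uniform; within a family, codon $c$ is
  chosen with probability $\propto \exp(\beta_g w_c)$, with per-gene
  selection strength $\beta_g \sim \mathrm{Exp}(\mathrm{mean}\ 2)$, gene
  lengths log-normal around ~350 codons clamped to [100, 1500] (fungal CDS
  scale), 2000 genes. $\beta = 0$ gives uniform synonymous usage
  (Nc → 61); large $\beta$ gives all-optimal codons (AAtAI → 1). Softmax in
  $w$ is a modeling convenience that makes every index respond
  monotonically to one knob — not a claim about the organism.
* **Expression** — baseline log2 signals $\sim N(10, 1.2)$; 15% of genes
  induced ($\ge$ 2-fold, small p), drawn from the top $\beta$ tertile; 12%
  repressed and 12% significantly-but-sub-twofold shifted, both
  $\beta$-neutral; background p ~ Uniform(0,1) so the false-positive inflow
  into groups C/D is analytic. The repressed and shifted fractions keep all
  four groups above 200 genes at the default size — the regime in which the
  group-comparison signature is asserted — and mirror real two-condition
  data, where most significant genes change less than two-fold.

Everything flows from one integer seed (each generator stage uses a fixed
offset of it); identical seeds give byte-identical files.

What passing synthetic tests does **not** show: the generator has i.i.d.
codons within genes, one global tRNA pool, no GC/mutational-bias gradient,
no amino-acid composition structure, and no length–expression coupling, so
recovering the signature here validates the pipeline's arithmetic and
statistics, not any biological claim about real genomes.

## Numerical choices and degenerate inputs

* Geometric means are computed in log space; indices are exact to ~1e-15
  against literal transcriptions of the formulas (asserted to 1e-10 in the
  suite).
* CPS is computed from raw counts (the per-thousand factors cancel
  exactly); a corpus in which every pair sits at its independence
  expectation scores 0 for every pair.
* Genes of one codon have undefined CPB (NA, warned); genes too short to
  observe any degeneracy class have undefined Nc.
* Rejected records (CDS validation, tRNA pseudogenes/undetermined
  anticodons, malformed expression rows) are dropped individually with
  logged reasons; nothing is silently lost. Isotype/anticodon discordance
  in the tRNA table is resolved in favor of the anticodon (the adaptiveness
  model is anticodon-driven), with a warning.
* Ties at the classification boundaries are fixed by policy (ratio exactly
  at the fold threshold is A/B; p exactly at alpha is C).

## Known limitations

* CPB carries the weakest group signal in the synthetic study: with i.i.d.
  codon choice, pair-level bias exists only through cross-gene aggregation
  (genes rich in optimal codons elevate optimal *pairs* jointly), a
  second-order effect. Group medians order correctly at every seed tried,
  but the B-vs-A/B-vs-D Mann–Whitney p for CPB fluctuates around 1e-4–3e-2
  across seeds; real genomes have intrinsic pair preferences the generator
  does not model.
* tGCN is a proxy for tRNA abundance; the wobble constraints are taken from
  the literature defaults rather than re-optimized against expression data.
* Only the standard nuclear genetic code is exercised by the validation
  suite; other NCBI table ids are accepted but untested.

## Problem sizes

The shipped tests run the full pipeline at 2000 genes (~700k codons) plus
smaller unit fixtures; the whole suite takes well under a minute, and
`scripts/acceptance.R` about ten seconds, on one CPU.
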