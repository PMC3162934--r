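---
title: "Methods: frequency-sum motif scoring and the Sigma-54 comparative pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-sum motif scoring and the Sigma-54 comparative pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sms54)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices taken where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The similarity model

### Frequency-sum scoring

Given `m >= 1` aligned sites of common length `i` over an alphabet (DNA or
the 20 standard amino acids), the position frequency matrix holds the raw
fraction `f_N(j)` of symbol `N` at column `j`. A candidate sequence `s` of
length `i` receives

```
SMS(s) = (1/i) * sum_j f_{s[j]}(j)
```

a number in `[0, 1]` that reads directly as similarity to the input set:
1 means every position shows a symbol that is universal in the input, 0
means none does. Three consequences drive the rest of the design:

* **No pseudocounts, ever.** A symbol absent from the input contributes
  exactly 0. Probabilistic scorers must regularize zero frequencies;
  here the absence of artificial scores is the point of the method, so
  fully conserved columns stay fully conserved. Sites sampled from the
  motif itself can therefore score exactly 1.
* **The maximum obtainable score** is the mean of the column maxima —
  the supremum of `SMS` over all length-`i` strings, attained exactly by
  any column-argmax string. Scan thresholds are expressed as a fraction
  of this value (default 0.85), which makes them transferable between
  motifs of different degeneracy.
* **Degeneracy is read off the build set.** Scoring the input sites
  against their own matrix gives per-site deviations from 1, and the mean
  build-set score collapses to the closed form
  `(1/i) * sum_j sum_N f_N(j)^2` — an identity the test suite checks
  exactly, because it only holds when no smoothing or regularization has
  touched the frequencies.

Out-of-alphabet symbols (N, IUPAC ambiguity codes, X, selenocysteine U,
pyrrolysine O) contribute 0. This is conservative: an ambiguous position
can only lower a score, never create a hit.

### Motif reduction

Raw promoter alignments carry flanking and internal columns that are
essentially random. `smooth_and_trim_pfm()` replaces columns whose
information content `sum_N f_N log2(f_N / bg_N)` falls below a threshold
(default **0.2 bits** against a uniform background) with the background
distribution, and removes maximal uninformative runs at the motif's ends,
re-indexing the -11 anchor. The 0.2-bit default is a configuration value,
not a derived constant: "rather random" has no canonical quantification,
so the threshold is exposed and documented rather than hidden.

## 2. Promoter scanning and the distance convention

The scanner scores every window on both strands (minus strand on the
reverse complement) and keeps windows at `>= threshold_fraction *
max_score`. Overlapping hits and both-strand hits at one span are all
kept — occurrences are counted, not collapsed. Ranks are per genome,
descending by score, ties broken by genomic position so reruns are
byte-stable.

Every hit is linked to the nearest gene **on each chromosomal side**,
located by translation start. The signed distance runs from the motif's
**-11 column** to the translation start, measured along the hit's reading
direction: positive means the start lies downstream of the promoter;
a start behind the -11 position (the element inside or past the gene
start) gives a negative distance. A link is `inline` when gene and hit
share a strand. Putative promoters are inline links with distance in
`[-50, 300]`; the top-15 rank cut is **not** applied to the genome-wide
promoter table but only where the context stage consumes promoters, and
both knobs are exposed.

The distance histogram uses half-open 100-nt bins `[k*100, (k+1)*100)`
split by orientation, with the grand total over both series normalized
to 1 — so inline and opposing series are comparable within one panel.

## 3. EBP identification

Candidates arrive as 12-column tabular homology results of 34 verified
seed activators against each proteome. Per protein, a 34-long e-value
vector is assembled: duplicate hits keep the minimum, seeds with no hit
are imputed at **10** (the classic reporting ceiling for an absent BLAST
hit; configurable), and reported zeros are floored at **1e-200** so
log-space arithmetic stays finite. The two filters are

* product of all 34 e-values < 1e-5, evaluated as `sum log10(e) < -5`
  (a naive double-precision product underflows for genuine profiles —
  34 values of 1e-10 are already 1e-340);
* sum of all 34 e-values < 1.

The imputation value matters: with 10 per missing seed, a protein missed
by more than a few seeds cannot pass the sum filter regardless of how
strong its remaining hits are, which is the intended behaviour for
paralogs hit by only one or two seeds.

### GAFTGA integrity

The hexapeptide loop that contacts Sigma-54 is located by protein SMS
against a strict `GAFTGA` consensus (frequency 1 per column; a
user-supplied protein PFM overrides, since the seed alignment itself is
not a published constant). Deletions are detected by additionally
scanning length-5 windows against the 6-column motif with one column
skipped, still dividing by 6; a gapped call wins only when it strictly
beats the best full-length window, so `GAFPGA` (5/6 as a full window)
is preferred over any gapped reading. Classification is per position
from a substitution-rule table compiling the experimentally observed
variants (G1→N, A2→S, F3→Y, T4→S/E, G5→D, A6→S functional; chemically
conservative sets putative; everything else — and any deletion —
inactive). The window is functional only if all six positions are,
putative if none is inactive, inactive otherwise. One documented tension:
T4→E is listed functional (PhhR) although organisms carrying it without
Sigma-54 suggest the substitution may divert the protein to Sigma-70
dependence; the rule table follows the tabulated call.

### Architecture and coarse annotation

Domain lists (N→C order) are typed with precedence **II > Ia > Ib > Ic**:
II on any PTS-related phosphorylatable domain (PRD / PTS-EII); Ia when a
response-regulator receiver domain precedes the central activator domain
and an HTH_8 DNA-binding domain is present; Ib for any other signal
domain plus HTH_8; Ic when the signal or DNA-binding domain is missing —
and, as a heuristic for unannotated proteins, whenever the chain is
shorter than 400 residues. The precedence ordering is a package choice:
the four types are usually presented as disjoint without a resolution
rule, yet type II proteins also contain the domains that would qualify
them as Ia/Ib. Coarse annotation assigns the label of the minimum-e-value seed,
with a 1e-20 cutoff (below which "similar to a verified EBP" is not a
defensible statement) and lexicographic tie-breaking.

## 4. Survey and context conventions

* **Discrete SD**: the per-phylum EBP count is reported as mean ± sample
  standard deviation, both rounded to the nearest integer — the
  convention fixed here for "discrete standard deviation", which has no
  agreed formula.
* **Size bins** are half-open `[k Mb, (k+1) Mb)`; a 2,000,000-bp genome
  is in bin 2.
* **Motile fractions** are computed over genomes with known motility
  only; an all-unknown bin reports NA rather than 0.
* **Operons** are maximal same-strand runs with intergenic gaps ≤ 300 nt
  (300 joins, 301 splits); same-strand overlapping genes merge.
  **Divergons** are adjacent head-to-head unit pairs (left unit on '-',
  right on '+') whose shared upstream stretch is ≤ 300 nt — a geometry
  the field names without defining, fixed here.
* **Context windows**: ±10 genes around Sigma-54/EBP genes; for
  promoters, the downstream unit in reading order capped at 10 plus one
  upstream gene. A gene occurring in several windows counts once per
  occurrence — context windows are evidence units, and deduplicating
  across them would weight isolated anchors over clustered ones.
* **Conserved tendencies**: per phylum and annotation type, the top-K
  terms by count (K = 20 when the phylum contributed ≥ 10 genomes, else
  10 — the genome-count switch is configurable because "top 10 or 20,
  depending on number of genomes" pins down no exact rule);
  boundary ties are all included rather than cut arbitrarily; a term
  qualifies when top-K in ≥ 2 phyla. Raising `min_phyla` can only remove
  terms (monotonicity is property-tested).
* **COG representation** uses a one-sided binomial test at 0.05 against
  the background category fraction; "+" requires both observed > expected
  and significance. No particular statistic is canonical for this
  comparison; a binomial on annotation draws is the minimal model
  consistent with it.

## 5. The synthetic world

The generator is first-class, tested code, and its defaults are a stated
world — they are not tuned against test outcomes.

* **Genomes** (default 200 kb, GC 0.5, 60 genes): genes laid left to
  right; 60% of gaps drawn from 20–200 nt (within-operon), 40% from
  400–900 nt (between units), so the 300-nt criterion separates the two
  regimes with a deliberate hole around the boundary; strand constant
  within a unit, random between units.
* **Planted promoters**: the motif's argmax string written inline
  upstream of randomly chosen unit-leading genes at signed distances
  drawn from `[-50, 300]` — by construction they score exactly
  `max_score` and satisfy the window filter. Decoy motif copies go into
  the gene-free leading margin, > 300 nt from any translation start.
* **Default motif**: a synthetic 16-column element with two conserved
  blocks (dominant frequency 0.94) around a mildly AT-rich degenerate
  spacer, mimicking the bipartite -24/-12 shape, with the -11 anchor in
  the downstream block. The genuine published matrix is not printed
  anywhere, so the motif is an input everywhere in the package; the
  synthetic one exists to exercise the machinery.
* **Proteins**: true EBPs embed chosen GAFTGA variants in scaffolds that
  exclude F (so no accidental full-scoring window precedes the plant)
  and carry one of the four canonical architectures; their 34-seed
  profiles are log-uniform in `[1e-150, 1e-25]` (pass both filters by
  orders of magnitude). Decoys hit only 1–3 seeds weakly
  (`[1e-6, 1]`), so imputation alone drives their sum far above 1.
  E-values are modeled directly; no alignment is simulated.
* **Annotations**: every gene draws baseline COG terms and a COG
  category from a shared vocabulary; designated terms are over-planted on
  the context-window genes of per-genome anchor genes in ≥ 2 phyla, plus
  a single-phylum control term.

What a green test does establish: the scoring identities, coordinate and
strand bookkeeping, filter arithmetic, grouping rules and end-to-end
determinism are correct on inputs whose ground truth is known exactly.
What it does not: real promoter alignments have correlated columns and
genuine e-value profiles have structure that log-uniform draws lack, so
recovery rates on synthetic plants say nothing about sensitivity or
specificity on real genomes.

## 6. Numerical and degenerate-input choices

* Scores are compared with a 1e-12 slack at the scan threshold so that a
  window tied with the cutoff by floating-point rounding is kept.
* Contigs shorter than the motif are skipped with a warning, not an
  error; a contig without genes yields zero links.
* `rank_hits` on an empty table returns an empty ranked table; histogram
  of zero links is empty rather than NaN-filled.
* A PFM whose columns are all uninformative cannot be trimmed — that is
  a degenerate-motif error, because scanning with a background-only
  matrix would rank every window equally.
* All internal coordinates are 0-based half-open; GFF3 and result TSVs
  are 1-based inclusive; the `tss_offset` anchor is 0-based (documented
  at every surface) to keep the invariant `0 <= tss_offset < i` literal.
* Derived RNG substreams are `(seed * 1000 + offset) mod (2^31 - 1)`,
  keeping every seed a valid 32-bit integer.

## 7. Known limitations

* The nearest-gene-per-side linkage assigns at most two links per hit;
  nested gene structures (genes within genes) would need richer logic.
* Divergon detection pairs units, but divergon membership is not used to
  extend promoter context beyond the downstream unit plus one upstream
  gene.
* The architecture typer trusts the provided domain vocabulary; it does
  not parse real PFAM output.
* `run_pipeline` maps contigs to genomes by name identity (one contig
  per genome, as the generator emits); multi-replicon genomes would need
  an explicit contig→genome table, and ranks would then still be per
  genome, not per replicon.
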