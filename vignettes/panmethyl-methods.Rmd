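---
title: "panmethyl: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panmethyl: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panmethyl)
```

This vignette documents the statistical and combinatorial models behind
`panmethyl`, the parameters that matter, the numerical conventions, and
the design decisions taken where more than one reasonable choice existed.
It states no empirical result that the package's test suite or acceptance
script does not itself compute.

## The K-OPL model

A lysine-oriented peptide library (K-OPL) for one methyl state is the set
of 9-mer peptide mixtures with a fixed central (methyl)lysine at position
5. Each *set* additionally fixes one amino acid at one flank offset
(P−3, P−2, P−1, P+1, P+2 or P+3); the remaining flank positions are
degenerate. With 19 candidate amino acids per position the library has
6 × 19 = 114 sets.

```{r}
lib <- kopl_library("me2")
nrow(lib)
table(lib$fixed_offset)
```

**Degenerate alphabet.** Cysteine is excluded from the fixed positions by
the library design; we exclude it from the degenerate positions too, for
consistency (disulfide chemistry makes Cys impractical on arrays). This
is a package decision, not a fact of the source data: membership tests
(`kopl_set_membership()`) treat any Cys in a flank as disqualifying.

**Peptide geometry.** The physical 9-mer has residues at ±4 from the
central lysine, but no set constrains them; all analysis operates on the
central 7-mer (K ± 3), and `set_id`s of the form `me2_P-1_F` are the join
key between the design and array scan tables.

## Array processing and the pan metric

Raw per-feature fluorescence is replicate-averaged (arithmetic mean; no
outlier rejection, since none is warranted without a replicate error
model) and divided by the **global maximum feature mean across the whole
slide** — including off-target methyl-state libraries printed alongside.
This global convention is what makes weak off-target binding visible as
sub-maximal signal. Two conventions are provided:

* `normalize_global()` — K-OPL selectivity profiles (default);
* `normalize_per_column()` — histone-peptide arrays, where each antibody
  column is scaled by its own maximum.

An ambiguity worth flagging: "highest signal" could mean the highest
feature *mean* or the highest single *replicate*. We use the highest
feature mean (the quantity actually plotted in heat maps); this is a
choice, not an established fact, and it only rescales profiles by a
constant close to 1.

The **pan metric score** summarizes sequence bias:

$$\mathrm{pan} = 100 \cdot \frac{1}{114} \sum_{(p, a)} M_{p,a}$$

over the normalized on-target matrix $M \in [0,1]^{19\times 6}$. A
saturated profile scores exactly 100, an empty one 0, and the score is
monotone in every cell. Off-target sets are deliberately excluded from
the average (the score measures bias *on the target state*; off-target
binding is a specificity question, not a pan-ness question). Degenerate
inputs fail loudly: an all-zero array raises an error rather than
returning a silent zero profile.

## PSSM scoring

The position-specific scoring matrix simply re-indexes the selectivity
profile: the *frequency score* of amino acid $a$ at offset $p$ is its
normalized on-target array signal. No log-odds transform, background
correction or pseudocount is applied — the array signal is already the
quantity of interest (relative binding preference), and any monotone
transform would leave the downstream *ranking* unchanged.

A lysine-centered 7-mer scores
$S(w) = \sum_{p} f(p, w_p)$, the sum of six lookups, so scores live in
$[0, 6]$. Conventions:

* **Cysteine** was never measured; its entries are explicit `NA` and
  contribute 0. Windows containing Cys are scored, not dropped.
* **Terminal lysines** (within 3 residues of a protein end) get windows
  padded with `X`, which contributes 0; `lysine_windows(pad = FALSE)`
  drops them instead. Padding slightly deflates terminal-site scores but
  keeps the one-record-per-lysine conservation property exact.
* **Ties** in `rank_proteome()` break by (accession, position), making
  ranks reproducible across runs and platforms.

## Site calling

Methyl modifications below the localization-probability threshold
(default **0.75**, configurable — the conventional "high confidence"
cut for PTM localization scores) are removed; records are never dropped,
so QC denominators stay intact. Site coordinates are
`protein_start + residue_index − 1` (1-based, reference-catalog
convention). The default site key is **(accession, position, state)** —
per-state novelty accounting implies state-aware identity — with a
`collapse_state` option for (accession, position); collapsing can only
reduce the site count, never increase it. When a proteome is supplied,
sites mapping to a non-lysine are quarantined into a mapping-error table
rather than silently discarded.

## Motif statistic

For a site set $d$ and background $p$ the motif matrix is
$\log_2(f^d_{p,a} / f^p_{p,a})$, where frequencies are per offset over
*observed* residues: window positions lost to protein termini are
excluded from the denominator (padding is not a residue). Cells with a
zero dataset count are **missing**, not $-\infty$ — absence of detection
is not evidence of depletion; cells with positive dataset frequency but
zero background frequency are flagged as infinite enrichment and reported
separately. No pseudocount by default (an optional `pseudocount`
argument exists for downstream visualisation). P0 is excluded — it is
always lysine by construction.

## Crosstalk proximity

For each methyl site and reference PTM type, a hit at offset $d$ means
the reference holds that PTM at position ±$d$ on the same accession.
Offsets are unsigned by default (a `signed` flag exists), window default
9. Per-offset percentages count each site once per (type, offset); the
overall within-window figure is a site-level union (a site with hits at
three offsets counts once). Offset 0 is reported for every type,
including phosphorylation — where it must be 0 (lysine cannot be
phosphorylated), a built-in sanity check the simulator honors.

## Compartment statistics

The two-proportion z-test uses the pooled variance form
$z = (\hat p_1 - \hat p_2)/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$ with
two-sided normal p-values; equal proportions return exactly $z = 0$
(including the degenerate pooled-0/1 case, where the naive formula is
0/0). No multiple-testing correction by default; a Bonferroni flag is
provided. Compartment membership uses score ≥ 3 (inclusive), the
stringApp-style convention.

## The synthetic world

The generators state a world once and the tests measure it; none of the
following values were adjusted after seeing a test outcome.

* **Proteome** (`gen_proteome()`): i.i.d. sequences with UniProt-average
  human residue frequencies, lognormal lengths (CV 45%, floor 50) around
  a 450-residue mean, 300 proteins by default.
* **Arrays** (`truth_antibody()`, `sim_kopl_array()`): expected signal =
  global intensity × state cross-reactivity × cell preference; Beta-
  distributed preferences with mean 0.35 (most real antibodies are
  substantially biased; the expected pan metric is then ~35), optional
  boosted cells for strong position-specific bias; multiplicative
  lognormal replicate noise of unit mean, CV 0.2, 3 replicates.
  Lognormal noise is the natural non-negative, scale-free choice for
  fluorescence.
* **Methylome** (`sim_methylome()`): per-state site rates (2%/1.2%/0.8%
  of lysines for me1/me2/me3 — a few hundred sites on the default
  proteome, the scale of a single-cell-line study), at most one state
  per lysine; a 40% reference fraction (60% true novelty, matching the
  novelty scale reported for di/tri-methyl); crosstalk PTMs planted with
  acetyl/ubiquityl mass concentrated at offset 0 (direct competition),
  phospho spread uniformly over offsets 1–9.
* **PSM tables** (`sim_psm_table()`): tryptic digestion in which
  methylated lysines block cleavage (di-methyl may not fully block in
  reality; decoys and missed cleavages are not modeled beyond this);
  capture probability `plogis(qlogis(capture) + bias · z)` with z the
  standardized PSSM score — the simplest monotone link that makes bias
  detection testable, and exactly uniform at bias 0; localization
  probabilities Beta(18, 1.5) for true sites (mostly above 0.75) and
  Beta(2, 6) for decoys (mostly below); decoy rate 0.002 of background
  PSMs; 20% phospho co-occurrence on methyl peptides. Default strategy
  design: one unenriched run (capture 0.03, 4000 background PSMs) and
  one enriched run per state (capture 0.55, 900 background PSMs), which
  lands enriched runs above a few percent methyl PSMs with the dominant
  state matching the target, and unenriched runs below one percent.

**What a green test does and does not establish.** The simulator
reproduces the *accounting structure* of enrichment proteomics — site
arithmetic, overlap, novelty, bias, QC ratios — with known truth. It does
not emulate spectra, peptide abundance, homologous sequence families,
isoforms, FDR behaviour of real search engines, or biological motif
structure beyond what is planted. Green tests certify the analysis chain,
not any biological claim.

## Numerical conventions and degenerate inputs

* Normalization is idempotent and scale-invariant (tested as properties).
* All-zero arrays/columns, empty proteomes, empty accession
  restrictions, <3-point correlations and zero-PSM runs raise or flag —
  never silently return 0.
* Correlations on constant vectors are returned as `NA` with a
  `degenerate`/`insufficient` flag.
* All generators are deterministic under a fixed seed, and `set.seed()`
  is called inside each generator, making every simulated object
  reproducible in isolation.

## Known limitations

* The pan metric averages the *target-state* library only; antibodies
  with severe off-target-state binding need the off-target profile
  inspected separately.
* Accessions are compared verbatim; no isoform collapsing.
* The PSM simulator emits at most one missed-cleavage pattern (the
  methyl-blocked one); real data contain more.
* Motif significance testing is out of scope — the matrix is a
  descriptive statistic.
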