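---
title: "Scanning alignments for divergent regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning alignments for divergent regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## The problem

Nearly all alignment analysis asks where sequences agree. divscan asks the
opposite question: in a multiple sequence alignment (MSA) of *closely
related* DNA or protein sequences — paralogous gene family members,
orthologs across a few species, isoforms — where are the small stretches
that *differ*? Those stretches are what you need for isoform-specific qPCR
primers, genotyping markers, probes, and peptide epitopes that distinguish
near-identical proteins. Because the sequences are similar by construction,
the signal is sparse: most columns are invariant, and the few divergent
columns cluster into short regions that are easy to miss by eye.

The pipeline is: read the MSA → trim unreliable gappy ends → build a
per-column frequency table → choose a reference (consensus or a designated
master sequence) → score every column → derive robust cutoffs → smooth the
score track → call putative SNPs (raw track) and conserved/divergent
regions (smoothed track) → optionally grade PCR primer windows over the
divergent regions.

## Column scores

All four methods consume the same per-column frequency table: with
$\gamma(i,b)$ the count of symbol $b$ at column $i$, $D(i)$ the number of
distinct symbols there, $C(i)$ the reference symbol, and $n$ the number of
sequences. Conserved columns score high (or zero), divergent columns score
negative. The exact closed forms below are this package's definitions;
they were fixed once from the methods' published descriptions
(identity-promoting weighting; the 1/0 simplification; sign-switched
entropy; any-change counting) and the normalisation by $n$ was chosen so
that DNAW is a fraction in $[0,1]$.

* **weighted** — $S(i) = \frac{1}{n}\sum_b \gamma(i,b)\,M(C(i),b)$ with a
  substitution matrix $M$: `identity` (+5 match / −4 mismatch over ACGT),
  `simple` (identity extended to IUPAC ambiguity codes, an ambiguous
  symbol scoring the mean of its expansion), or BLOSUM62 for proteins.
  Any pairing that involves a gap scores the matrix's minimum
  off-diagonal entry — a gap is treated as the least conserving
  substitution, because there is no accepted substitution model for gaps.
* **dnaw** — the DNA-only 1/0 simplification:
  $S(i) = \gamma(i, C(i))/n \in [0,1]$, the fraction of sequences that
  match the reference. When the reference symbol at a column is a gap
  (possible in master mode) there is no reference base to match and the
  score is 0.
* **entropy** — $S(i) = -H(i)$ with
  $H(i) = -\sum_b f(b)\log_2 f(b)$, $f(b)=\gamma(i,b)/n$, the gap counted
  as a symbol class. $S \le 0$ with equality exactly for uniform columns.
  Base 2 (bits) is the sequence-logo convention; the base is a parameter.
* **variability** — $S(i) = 1 - D(i)$: one unit more negative per extra
  symbol observed, blind to how conservative each change is.

Scoring is driven entirely by the frequency table, so its cost per column
is independent of the number of sequences once the table is built; the
table is built in one pass.

### Reference track

By default the reference is the consensus: the most frequent non-gap
symbol per column, ties broken to the lexicographically smallest symbol
(the plurality threshold is configurable and defaults to 0, i.e. plain
plurality; the tie rule is this package's choice and is deliberately
deterministic). Gaps never win a consensus call except in all-gap
columns. Naming a **master** sequence replaces the consensus with that
row's own residues, turning every score into "how different is everyone
from *this* sequence" — the right question when designing a probe
specific to one family member.

## End slicing

MSA ends usually carry a high proportion of gaps (ragged starts and
ends), where frequencies are computed over few sequences and alignment
quality is poor. Each end is trimmed inward until two contiguous columns
are entirely gap-free; analysis covers the span from the first such pair
to the last. Manual bounds override the automatic rule after validation.
If no two contiguous gap-free columns exist the alignment is rejected as
too gappy.

## Cutoffs

Score distributions here are spiky and heavily concentrated at the
conserved value, so spread is estimated robustly. With
$\mathrm{MAD} = \mathrm{median}(|X - \mathrm{median}(X)|)$, the cutoffs
are $\mathrm{median}(X) \pm 1.4826\,\mathrm{MAD}$; the constant
$1.4826 \approx 1/\Phi^{-1}(3/4)$ makes the margin equivalent to one
standard deviation under normality. For very similar DNA sequences the
median and the MAD are typically both exactly zero (most columns are
invariant); the spread then falls back to the mean absolute deviation
about the mean, $\mathrm{MAD}_{mean} = \mathrm{mean}(|X -
\mathrm{mean}(X)|)$, which the overpopulated modal value cannot zero
out. Two choices in the fallback branch are deliberate: the same 1.4826
multiplier is kept (a single consistent margin definition, rather than
the 1.2533 mean-deviation consistency factor), and the margin stays
centred on the median for continuity with the main branch. In the
fallback only the low cutoff is usable — with a degenerate distribution
a high cutoff would not identify meaningful conservation, so only
divergent regions are callable.

## Smoothing and the two branches

Raw scores flag single columns; regions need a wider view. The raw track
is low-pass filtered by discrete Fourier transform: coefficients above
frequency index $\lceil L/(2w) \rceil$ are zeroed and the signal inverse
transformed, where $L$ is the track length and $w$ the window parameter
(default 10 columns, about the narrowest feature a primer-scale analysis
cares about). The filter is linear, preserves the mean exactly (the DC
coefficient is always kept), and uses hard truncation — a taper was
considered and rejected as an extra parameter with no observable benefit
at these track lengths.

The pipeline then splits into two branches, each thresholded with
cutoffs computed from its own track:

* **raw branch → putative SNPs (DNA only).** A column is a putative SNP
  iff its raw score is below the raw-track low cutoff, at least one
  non-reference symbol is present, and *every* non-reference symbol
  present occurs in ≥ 2 sequences (a single-copy variant is
  indistinguishable from a sequencing error). This is the strictest
  reading of the evidence rule, and it implies that alignments of fewer
  than four sequences cannot support SNP prediction; that consequence is
  also enforced directly so it holds in master mode, where the master's
  own minority residue could otherwise fabricate a qualifying column.
  Gap-only variation may qualify a column (gaps are symbol classes);
  this is configurable off. Synonymy and structural effects are
  explicitly not assessed.
* **smoothed branch → regions.** Divergent candidates are maximal runs
  of columns with smoothed score below the smoothed-track low cutoff;
  conserved candidates are runs above its high cutoff (none in the
  fallback regime). For DNA, a divergent candidate must contain at
  least two putative SNP columns or it is discarded; protein regions
  have no SNP requirement and no minimum length beyond one column. A
  region's characteristic score is the arithmetic mean of the *raw*
  scores of its columns.

Reported regions are bucketed by length: fewer than 6 positions, 6–11,
or more than 11.

## Primer windows and grading

Each divergent region, mapped through the reference's gaps onto ungapped
reference coordinates, plus five nucleotides of flank on each side,
defines a default primer window (clamped at the sequence ends). A window
sequence — or any candidate primer — is measured and graded:

| property | PASS band | note |
|---|---|---|
| GC content | 40–60 % (inclusive) | reported rounded to integer |
| melting temperature | > 52 °C | nearest-neighbor, see below |
| 3' GC clamp | 2–3 G/C in last 5 bases | the common clamp convention |
| repeats | none | mononucleotide run ≥ 4, or dinucleotide motif ×4 |
| self-dimer ΔG | > −4 kcal/mol | simplified model, see below |
| hairpin ΔG | > −3 kcal/mol | simplified model, see below |

Values just outside a band grade WARN (margins: 5 GC points, 2 °C,
1 kcal/mol; configurable), everything further FAIL — a traffic-light
summary rather than a hard filter, since a user can always shift or
resize the window and re-grade.

Melting temperature uses nearest-neighbor thermodynamics with the
SantaLucia unified parameter set, 50 mM monovalent salt and 500 nM
primer by default (a Wallace-rule fallback is available). Different Tm
conventions differ by several degrees; the published primer sets this
package uses as test vectors were verified for length and GC content
exactly, while their printed Tm values track ours with an offset of
2–3 °C, consistent with a different (unknown) Tm convention at the
source — so Tm agreement is checked loosely, not exactly.

Secondary-structure free energies are deliberately simplified: the
minimum over all ungapped antiparallel self-alignments (dimer) or over
all outward-extended stems with loop ≥ 3 (hairpin) of the summed
nearest-neighbor stack energies of perfect-complement stretches, with no
internal loop, bulge or loop-entropy terms. This is a conservative
screen adequate for threshold grading, not a folding prediction;
sequences flagged here may still be usable, and a dedicated
thermodynamic folder is the right tool for borderline calls.

Degenerate-primer design is intentionally unsupported: these primers
exist to identify one specific sequence.

## Synthetic data: what it emulates and what it does not

`generate_msa()` plants known structure: outside designated blocks all
sequences are identical; inside a block each column independently (with
probability `variant_fraction`) assigns one alternative base to a random
subset of 2 up to ⌊(nseq−1)/2⌋ of the non-reference sequences, so the
reference row keeps the plurality and every planted variant satisfies
the ≥ 2-copy evidence rule by construction. Terminal gap wedges exercise
end slicing. Sequence 1 is the unmutated reference, so ground truth is
exact, and a fixed seed makes output byte-identical.

This emulates the target regime — near-identical sequences with short
clustered divergence — but not real evolution: there is no substitution
model, no transition/transversion bias, no indel evolution, no rate
variation, and variants within a column are always a single alternative
base. Passing the recovery tests therefore shows the calling machinery
is correct under the stated model, not that the method's biological
error rates on real gene families match any particular figure.

The standard recovery conditions used by the tests and the acceptance
script are 8 sequences × 500 columns with three planted blocks of
lengths 6, 10 and 15 at `variant_fraction` 0.5, across 20 seeds — small
enough to run in seconds, large enough that block recovery and false
calls outside blocks are meaningful. Under these conditions the entropy
pipeline recovers ≥ 90 % of planted blocks and calls no divergent
region wholly outside them; divergent columns called by the weighted
score are ≥ 95 % covered by entropy's calls, the expected ordering since
weighted is the most restrictive method and entropy the most inclusive.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere — internally, in reports,
  and in GFF3 — matching R convention and the GFF3 spec; off-by-one bugs
  from a mixed convention cost more than the half-open arithmetic saves.
* Format detection reads content signatures (`>`, `CLUSTAL`, `#NEXUS`,
  numeric PHYLIP header, `MSF:`), never the file name; an explicit
  format hint is used only when sniffing is inconclusive, so a
  misleading hint cannot misparse a recognisable file.
* `.` gaps normalize to `-`; residues fold to upper case; IUPAC
  ambiguity codes are retained as symbols. An alignment is DNA when
  > 90 % of its non-gap characters are IUPAC nucleotide symbols.
* Median of an even-length vector is the mean of the two central order
  statistics (R's default).
* The MAD-collapse tolerance is 1e-12: the fallback should trigger on
  exact structural zeros, not on rounding noise.
* All randomness lives in the fixture generator and is seed-controlled;
  the analysis pipeline itself is fully deterministic, and identical
  input plus identical configuration yields byte-identical JSON bundles.

## Known limitations

* Scores are column-independent: no phylogenetic weighting, so a variant
  shared by a clade counts the same as one scattered across the tree.
* The DNAW score of a region is reported as the plain mean of column
  match fractions; published per-region values of the analogous score
  elsewhere appear to be on a different (unstated) scale, so DNAW region
  scores should be compared within a run, not across tools.
* The Tm and ΔG models are screening approximations (see above).
* Hyper-variable gappy ends are sliced away, which is correct for primer
  work inside the aligned core but discards regions that could serve as
  blot probes; manual slice bounds recover them if wanted.
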