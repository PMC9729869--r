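---
title: "Characterizing a GGPPS gene: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a GGPPS gene: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggppschar)
```

Geranylgeranyl diphosphate synthase (GGPPS) sits at the entry point of
carotenoid biosynthesis: it condenses isopentenyl diphosphate with an
allylic substrate into the C20 precursor GGPP, and in carotenogenic fungi
it is encoded by *crtE*. When such a gene is cloned, the standard dry-lab
characterization answers four questions: how is the gene spliced, what
protein does it encode, which prenyltransferase motifs does the protein
carry, and which GGPPS type is it. `ggppschar` implements that workflow as
testable, seeded, offline-capable functions. This vignette explains the
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
corner cases.

## Spliced alignment and the GT-AG audit

**Model.** The cDNA is assumed to be the concatenation of exons of the
genomic sequence, co-oriented with it (forward strand only), with only
substitutional divergence inside exons. Under that model an alignment is an
ordered exon chain: a partition of the cDNA into segments, each mapped
ungapped at one genomic offset, with genomic gaps (introns) between
consecutive segments. The chain score is

$$S = m_{+}\cdot\text{match} - m_{-}\cdot\text{mismatch}
      - k\cdot\text{intron\_open} + c\cdot\text{canonical\_bonus},$$

where $m_+$, $m_-$ count matched/mismatched bases, $k$ is the number of
introns and $c$ the number whose donor is `GT` and acceptor `AG`.
Spliceosomal introns overwhelmingly follow the GT-AG rule, so the bonus
both disambiguates junction placement and encodes the biological prior; no
further splice signal (branch point, GC-AG donors) is modeled.

**Defaults and why.** `match = 1`, `mismatch = 2`, `intron_open = 8`,
`canonical_bonus = 4`, `min_intron = 20` nt, `min_identity = 0.95`. The
intron penalty strongly prefers fewer introns (parsimony), the bonus makes
a canonical placement beat any single-base rearrangement (a one-base shift
can gain at most `match + mismatch = 3 < 4`), `min_intron = 20` is below
any plausible fungal intron yet blocks spurious micro-introns, and the
identity floor rejects mappings of transcripts that are not the gene's own
cDNA. None of these values is sensitive for near-identity inputs; all are
exposed via `align_params()`.

**Engines.** For inputs whose combined length exceeds `dp_max_combined`
(2,000 nt), the aligner seeds exact k-mer anchors (`k = 12`), groups them
by diagonal, chains them collinearly, and then places each junction at the
split point that maximizes the local score — enumerating every split
between adjacent anchored cores plus a 6 nt margin, so the placement is
exact given the chained diagonals. For small inputs (and whenever the cDNA
is too short to anchor), an exhaustive two-state dynamic program over
(exon, intron) states computes the global optimum directly; the unit tests
hold the two engines and an independent brute-force enumeration of all exon
chains to the same score on small instances. Ties between equal-score
models prefer fewer introns, then canonical junctions, then the leftmost
donor — `refine_boundaries()` applies the same policy as a separate,
score-non-decreasing pass, which is also the documented way to resolve the
junction ambiguity that arises when sequence context repeats across a
junction.

**Choice of k.** With ≤ 2% exon divergence, clean 12-mers occur every few
dozen bases inside exons of ≥ 30 nt, while random 12-mer collisions in a
few-kb locus are rare (expected ≪ 1); `k = 12` therefore separates signal
anchors from noise without a masking step.

## ORF, mass and isoelectric point

`find_orf()` returns the longest complete ATG..stop reading frame on the
forward strand (ties: smallest start). "Longest complete ORF" is the
appropriate policy for a full-length cDNA clone of a single gene; the
package deliberately has no partial-ORF or reverse-strand mode.

Molecular mass is the sum of *average* residue masses plus one water
(18.01524 Da), the convention of standard protein property calculators;
monoisotopic masses would differ by tens of Da at this protein size.

The isoelectric point is defined as the pH at which the net charge

$$Q(\mathrm{pH}) = \sum_{\text{basic } g} \frac{1}{1+10^{\mathrm{pH}-pK_g}}
 - \sum_{\text{acidic } g} \frac{1}{1+10^{pK_g-\mathrm{pH}}}$$

vanishes, with groups = N-terminal amine, C-terminal carboxyl and the side
chains of H, K, R (basic) and D, E, C, Y (acidic). The pKa set is the
Bjellqvist calibration used by the common ProtParam-style tools, including
its residue-specific N-terminal values and its C-terminal adjustments for
terminal Asp/Glu (`pka_bjellqvist()`; a modified table can be passed in or
set via the config file). Since every term is strictly decreasing in pH,
the root is unique and bisection on [0, 14] converges unconditionally; we
iterate to |Q| < 1e-4 and report two decimals. One caveat worth recording:
some popular implementations restrict their search to pH ≳ 4, which silently
clamps strongly acidic peptides; the tests therefore cross-check frozen
external values only where those are genuine roots, and use a dense-grid
search oracle elsewhere.

## FARM, SARM, CLD and the type rules

Trans-prenyltransferases carry two aspartate-rich, Mg²⁺-chelating motifs.
The scanner searches the N-terminal 60% of the protein for the FARM
(`DDxxD` or `DDxxxxD`) and the C-terminal 60% for the SARM (`DDxxD`),
reports the first FARM that has a valid downstream SARM, and takes as SARM
the match closest to the C-terminus whose distance to the FARM start lies
in [80, 250] residues. The zone restriction prevents swapped assignments on
aspartate-rich sequences; the distance window brackets the two-motif
geometry of known short-chain prenyltransferases and is a package decision,
not a literature constant. When both FARM forms match at one position the
short form is recorded.

The chain-length determination region (CLD) is the FARM plus the five
residues immediately upstream. The classification rules are taken directly
from the field's taxonomy: type I (archaeal) enzymes have a `DDxxD` FARM
with an aromatic residue (F/Y/W) five positions upstream and a non-aromatic
one four positions upstream — the bulky aromatic ring is the floor of the
elongation cavity that stops the chain early; types II (plants, bacteria)
and III (animals, fungi) share a `DDxxxxD` FARM with small non-aromatic
−5/−4 residues. Because the stated II and III descriptions are identical,
the rule stage alone returns the joint candidate {II, III}, and the final
call is made by homology: the type II/III panel reference with the highest
CLD identity lends its type. "Aromatic with a large side chain" is
implemented as membership in {F, Y, W}; no size threshold beyond
aromaticity is defined anywhere we could anchor one. Conserved domains I,
III and IV of the classic five-domain GGPPS alignment have no printed
sequence definition, so the report lists them as "not assessed" rather than
inventing boundaries.

The bundled panel (`synthetic_panel_path()`) is **synthetic**: nine
constructed stand-ins carrying each type's CLD features, including a
fungal-type entry whose CLD is identical to the crtE surrogate's and a
human-like entry differing only at CLD −1. It exists so the pipeline and
its tests run offline; for real classifications it should be replaced by a
curated FASTA + TSV of reference GGPPS proteins.

`map_residues()` transfers annotated positions between homologs through a
global Needleman–Wunsch alignment with BLOSUM62 and affine gaps
(open 10, extend 1) — the standard parameterization for close homologs.
Positions opposite a gap map to `NA` rather than to a nearest neighbor.

## The synthetic-data generator

The generator is the package's stand-in for raw study data: it emulates a
compact fungal carotenogenic gene. Defaults — nine exons of 80–180 nt,
introns of 50–100 nt beginning `GT` and ending `AG`, substitution-only
divergence between cDNA and genomic exon copies, a single complete planted
ORF when a motif-bearing protein is requested, FARM–SARM distances drawn
from [90, 200] residues — mirror that architecture. `synthetic_crte_locus()`
additionally pins the published structural facts of the gene the package
was built around: 1,722 bp genomic / 1,134 bp cDNA, 9 exons / 8 GT-AG
introns, a 377-residue translation whose termini follow the cloning
primers, Ala/Ser at CLD −5/−4, a `DDxxxxD` FARM at residue 78 and bulky
Tyr110/Phe111/His141. It is labelled synthetic everywhere: its background
residues and codon choices are seeded-random, so derived properties such as
molecular mass or pI are properties of the surrogate, not of any deposited
sequence.

Two deliberate identifiability guarantees keep planted truth well-defined.
First, synthetic protein backgrounds exclude aspartate entirely, so the
only D-rich motifs are the planted ones. Second, when an intron is placed,
its interior is resampled if any junction shift within ±6 nt would tie the
planted placement's score with another canonical placement; without this, a
small but calculable fraction of random junctions (about 3% of nine-exon
genes) is genuinely ambiguous — no aligner could recover "the" planted
boundaries there, because several are equally right. Mutations are
substitutions only for the same reason; an indel mode exists for stress
testing but carries no recovery guarantee.

What the generator does **not** emulate: real splice-site consensus beyond
GT/AG, branch points, codon usage bias, repetitive or low-complexity
sequence, paralogs, and transcript ends (UTRs are minimal). Passing the
recovery suites therefore demonstrates correctness of the algorithms under
the stated model — near-identity, substitution-only, canonical-intron
genes — not performance on diverged or repeat-rich real loci.

## Problem sizes and reproducibility

The recovery experiments run 200 seeded replicates of the nine-exon
configuration at 2% exon divergence and 200 planted-CLD proteins; these
sizes give a resolution of 0.5 percentage points on the recovery rates
while keeping the whole suite fast on a single core. Exhaustive-enumeration
cross-checks use loci of ≤ 120 nt with ≤ 2 introns, where enumeration of
every exon chain is tractable. All generator entry points require an
explicit seed (the command-line wrapper defaults to 42 and logs it), and
`scripts/acceptance.R` derives every random stream from its `--seed`
argument, so every reported number is reproducible byte for byte.

## Known limitations

* Forward strand only, one isoform, no polyA handling; transcripts below
  95% identity to their locus are rejected by design.
* The GT-AG audit is descriptive: non-canonical junctions are reported, not
  "corrected", and only GT-AG (not GC-AG) earns the canonical bonus.
* Type II vs III separation is only as good as the supplied panel; with the
  bundled synthetic panel it demonstrates the mechanism, not a curated
  classification.
* The GenBank reader handles single-record flat files with simple or
  `join(..)` CDS locations; it is not a general-purpose GenBank parser.
* Config files are YAML; unknown keys are ignored rather than rejected.
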