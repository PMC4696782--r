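---
title: "Methods: in-silico neuropeptidome discovery with pepmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico neuropeptidome discovery with pepmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmine)
```

# The biological model

Neuropeptides are not encoded directly. A neural transcript encodes a
*precursor* protein with a stereotyped architecture: an N-terminal signal
peptide that routes the protein into the secretory pathway, followed by
alternating blocks of bioactive peptides and linker segments, separated by
short basic motifs at which prohormone convertases cut. Maturation then
trims the basic residues, converts C-terminal glycines into amides,
cyclizes N-terminal Gln/Glu into pyroglutamate, and — for some peptides —
adds tyrosine sulfate and disulfide bonds. `pepmine` implements this
grammar so that a transcript assembly can be turned into a predicted
peptidome, and the cognate receptors (mostly G-protein-coupled receptors)
can be recognized and characterized.

The pipeline deliberately separates three concerns:

1. **What the transcript supports** — six-frame translation, maximal
   stop-to-stop ORFs, and completeness classification from the ORF flags.
2. **What the enzymes would do** — cleavage, excision, and PTM rules
   applied to a deduced precursor.
3. **What the peptide is** — family classification by motif or exact
   structure.

## Completeness classification

Assemblies truncate transcripts, so a deduced protein may be incomplete.
The four-way scheme used throughout is a function of four flags — upstream
stop codon, start methionine, terminal stop codon, predicted signal
peptide:

| class | meaning | definition |
|---|---|---|
| F | full-length | upstream stop ∧ start Met ∧ terminal stop ∧ signal |
| F (putative) | full-length, 5′ end unproven | no upstream stop, otherwise as F |
| N | amino-terminal partial (C-terminus missing) | start Met ∧ signal ∧ no terminal stop |
| C | carboxyl-terminal partial (N-terminus missing) | no upstream stop ∧ no (Met + signal) ∧ terminal stop |
| I | internal fragment | everything else |

The classification is exhaustive and mutually exclusive over all flag
combinations (table-driven test). Open precursor ends propagate into the
excised peptides: the first fragment of a C/I-type precursor is flagged
`n_open`, the last fragment of an N/I-type precursor `c_open`, and both
render as `+` in the conventional notation.

## Signal peptides

Dedicated signal-peptide predictors are trained models whose internals
cannot be reproduced from a description, so `pepmine` provides two modes:

- a **documented heuristic**: an h-region of ≥ 7 consecutive residues from
  {A,I,L,F,V,M,W,C} beginning within the first 35 residues, then the first
  position after the h-region whose −3 and −1 residues are small
  ({A,G,S,C,T,V}), with the signal length constrained to 10–45 aa;
- an **annotation override** that accepts curated spans verbatim, so that
  externally validated signal peptides always win over the stand-in.

The heuristic is a transparent rendering of the classical von Heijne
architecture, not a re-implementation of any trained predictor; on real
proteins its calls should be reviewed or replaced by annotations.

## Cleavage rules

The default ruleset follows the standard prohormone-convertase
conventions for arthropod precursors:

- every `KR` and `RR` dibasic cleaves;
- `KK`/`RK` dibasics cleave when enabled (default on, flagged
  low-confidence, because real precursors honour them inconsistently);
- a monobasic `K`/`R` cleaves only when another basic residue sits at
  relative position −4, −6 or −8 and the next residue is not proline;
- no site inside the signal peptide; overlaps resolve leftmost-first and
  each residue belongs to at most one site.

An annotation mode accepts curated loci (0-based position of the first
basic residue) and infers widths from the sequence. The basic residues of
a site belong to neither flanking peptide, so the signal peptide, the
fragments, and the removed basics concatenate back to the precursor
exactly — a conservation property the tests enforce on every synthetic
precursor.

Enabling `KK`/`RK` is monotone at the level of *cleaved residues*: every
basic residue cleaved without the secondary dibasics stays cleaved with
them, though a mono site can be absorbed into a wider dibasic site when
three basics are adjacent. The tests check the residue-coverage form of
the property.

## Post-translational modifications

- **Amidation**: a fragment ending in G that was followed by a cleavage
  site loses the G and gains a C-terminal amide. At the precursor's own
  C-terminus (no following site) amidation needs a template entry, since
  in practice that call is made by homology to known isoforms.
- **Pyroglutamate**: N-terminal Q cyclizes on peptides with both ends
  intact; E cyclizes only via template by default (`ptm_config(pyroglu_E=)`
  offers `never`/`template`/`always`), because reference data show both
  pE- and plain-E peptides. Truncated peptides are left unmodified at the
  N-terminus — reference predictions treat partial peptides
  conservatively, and we follow that practice.
- **Sulfation and disulfides** are predicted only for full-length
  peptides. Sulfation comes exclusively from templates. Disulfides pair
  automatically only in the unambiguous two-cysteine case; richer
  connectivity (e.g. the three-bridge hyperglycemic-hormone pattern) comes
  from templates listing 1-based cysteine ordinals.

Distinctness of a peptide covers its sequence *and* its full
PTM/truncation state, so an amidated and a free-acid form of the same
sequence count as two peptides. Whether a published "distinct peptide"
total uses the same key is not always stated; the key here is explicit
and tested.

## Family classification

Family membership is decided by an ordered, editable motif library plus
exact-structure templates, with precedence: exact template → precursor
family (when its motif also matches) → first matching library motif →
partial-peptide matching on the intact end (≥ 4 residues) → linker. Order
resolves real collisions: the myosuppressin full-sequence motif precedes
the generic `[FY]LRF`-amide suffix, and `[FY]LRF` precedes the sulfakinin
`[HY][LM]RF` motif so that `...YLRFamide` peptides resolve to FLRFamide
while `...GHLRFamide` falls through to sulfakinin. Patterns use a small
explicit syntax (literals, classes, `.`, `{m,n}`) compiled to fixed-length
alternatives, which makes truncated-end matching well defined; `X`
(uncalled) never matches.

## Mining and receptor characterization

The translated search aligns a protein query locally (BLOSUM62, gap open
10, extend 0.5) against every stop-free segment of all six frame
translations — no alignment crosses a stop codon. E-values use
Karlin–Altschul scaling with the conventional gapped-BLOSUM62 constants
(λ = 0.267, K = 0.041) and the total translated database size. The default
cutoff E ≤ 5e-3 is a judgment call: weak but genuine precursor hits sit
around E ≈ 1e-3 in this problem domain, and the cutoff is configurable.
Raw scores of a proprietary or heuristic search engine are *not*
reproduced; the module guarantees ranking behaviour, which is what the
tests pin down (an embedded query always ranks its transcript first;
scores are order-invariant; E scales with database size).

When a transcript has several ORFs the candidate is the ORF overlapping
the best homology hit, else the longest. Length alone is unreliable:
the antisense frame of a coding region is itself depleted of stop codons
and frequently yields a longer stop-free stretch than the true protein.

Receptor superfamily calls are by homology: the reciprocal-best-hit panel
member's label wins, and the hydropathy-based transmembrane count
corroborates it (7 ± 1 segments is consistent with a GPCR; a discordant
count is reported, never overriding the label; partial proteins never
fail the check). Hydropathy uses the Kyte–Doolittle scale with its
canonical transmembrane settings — window 19, threshold 1.6 — plus a
minimum segment length of 15 and a merge gap of 3; all configurable.
Window sums are computed in exact integer tenths so threshold crossings
are reproducible under sequence translation. This is a transparent
stand-in for domain-database annotation, not a re-implementation of it;
domain-boundary-dependent statistics (e.g. identity within
database-defined TM regions) are out of scope.

## Conservation statistics

Global alignment is optimal dynamic programming under BLOSUM62 with
affine gaps 10/0.5 (a heuristic multiple aligner used interactively would
produce the same columns for pairs at the identity levels of interest;
the statistic's tolerance for aligner differences is ±1 percentage
point). Conservation symbols use the conventional Clustal strong/weak
groups, shipped as data and overridable. The identity and similarity
percentages divide by the *ungapped length of the longer sequence* — a
deliberate, literal reading of the conventional formula — and `.` columns
count as similar alongside `:`.

Correctness is established by two independent oracles: exhaustive
enumeration of every global alignment (tractable to ~6 aa, and used to
validate the second oracle) and an independently written plain-R
affine-gap DP, checked against the implementation on 200 random pairs up
to 12 aa. Full enumeration at 12×12 would require ~10^8 paths per pair
and is not attempted; the two-tier oracle design gives the same assurance
at a fraction of the cost.

# The synthetic-data generator

The generator is first-class, tested code. `generate_precursor()` builds
proteins with the canonical architecture — signal peptide (Met, two basic
residues, an 8–12 residue hydrophobic h-region, an `ASA` context
satisfying the (−3,−1) rule), then alternating peptide and linker blocks
separated by sites drawn from a configurable mix of `KR`, `RR` and
monobasic `R` (the −4 basic helper is engineered into the preceding
block). Family peptides instantiate the shipped motifs; amidation donors
are explicit trailing glycines; pyroglutamate is an explicit prepended
glutamine. Two constructions keep the ground truth unambiguous under the
default rules: motifs containing an internal arginine (FLRFamide,
pyrokinin) carry an N-terminal extension placing that arginine at block
index ≥ 8, out of reach of any −4/−6/−8 helper, and monobasic sites are
placed only after linker blocks, whose rebuild around the helper does not
destroy a family motif.

`generate_transcriptome()` back-translates precursors with uniform
synonymous codons, embeds them in random frames and strands with UTRs and
bracketing stops, and realizes a completeness mix by construction (N:
terminal stop and 3′ tail removed; C: 5′ end through the start Met
removed; I: both). Decoys are random sequence, length-matched and
GC-matched (within 2 percentage points) to the true set so that mining
specificity is meaningful. Everything is deterministic under a seed, and
the same seed yields byte-identical output.

**What the generator does not emulate** — codon usage bias, sequencing
error, chimeric or mis-assembled transcripts, alternative splicing,
signal-anchor proteins, non-canonical cleavage (e.g. at single histidine
or acidic-context sites), and precursors whose peptides genuinely violate
the default rules. Passing the round-trip tests therefore demonstrates
the internal consistency of rules, generator and pipeline — not that the
rules capture every real precursor. On real data, the annotation-override
modes exist precisely because curated knowledge must be able to overrule
every heuristic in the chain.

# Problem sizes and numerical choices

The shipped test suite and acceptance script use: 1,000 random precursors
for the excision-conservation check, a 40-transcript F/N/C/I mix for the
completeness confusion matrix, 100 precursors for rule-vs-annotation
cleavage agreement, 200 random pairs (≤ 12 aa) for the alignment oracle,
and a 10-true/50-decoy transcriptome for the mining round trip. These
sizes give fully deterministic, seconds-scale checks whose failure modes
are individually diagnosable; the statistics they measure (reconstruction
rate, confusion diagonal, precision/recall, oracle agreement, rank-1
recovery, decoy false positives) are the quantities the acceptance script
reports.

Other fixed choices: ORFs are maximal stop-to-stop stretches with
start-Met trimming deferred to the precursor stage (preserving the
ORF/protein distinction); coordinates are 0-based half-open everywhere;
the minimum precursor length defaults to 30 aa (the shortest credible
precursor fragments in reference data are in the mid-30s); codons
containing ambiguity translate to `X`, and `X` never matches a motif and
contributes zero hydropathy; alignment tie-breaking is delegated to the
deterministic optimal-alignment engine, and only scores and column
classes — never a particular co-optimal path — are asserted anywhere.

# Known limitations

- The signal-peptide heuristic is intentionally simple; its false
  negatives flip F→C and N→I classifications, which is why annotation
  mode exists and is used for curated data.
- Family motifs are a curated rendering of informally described consensus
  endings; new families require library edits (by design — the library is
  data, not code).
- The mining module guarantees ranking, not score equality with any
  external search engine.
- Receptor superfamily calls inherit the panel's labels; with no panel
  hit the superfamily is `unknown` regardless of a clean 7-TM profile.
- Multiple-sequence alignment is out of scope; conservation statistics
  are pairwise.
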