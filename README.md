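# pepmine

In-silico neuropeptidome and receptor discovery from transcriptome
assemblies.

Neuropeptides are the largest class of neurochemical signalling molecules,
but in most invertebrates they are known only indirectly: what a genome or
neural transcriptome actually encodes are *precursor* proteins
(pre/preprohormones) that the cell matures into peptides through a fixed
enzymatic grammar. `pepmine` implements that grammar as a reusable,
testable pipeline for researchers mining transcript assemblies (e.g. from
crustacean or insect nervous systems) for peptidergic signalling
components:

- **Mining** — translated local-alignment search (tblastn-style) of protein
  queries against all six reading frames of a transcript set, with
  Karlin–Altschul bit scores and E-values, and reciprocal-best-hit vetting
  against a labelled reference panel.
- **Precursor assessment** — ORF extraction with stop-bracketing flags, a
  documented signal-peptide heuristic (hydrophobic h-region plus the
  von Heijne (−3,−1) small-residue rule) with an annotation override, and
  the standard four-way completeness classification: **F** (full-length:
  stop codons bracket the ORF, start Met, signal peptide), **N**
  (amino-terminal partial: no terminal stop), **C** (carboxyl-terminal
  partial: no upstream stop, no start Met), **I** (internal fragment).
- **Peptide prediction** — prohormone-convertase cleavage at mono- and
  dibasic loci (KR/RR always; KK/RK optional, low-confidence; monobasic
  K/R only with a basic helper at −4/−6/−8 and no following Pro), peptide
  excision with conservation of every residue, and post-translational
  decoration: C-terminal amidation at glycine donors, N-terminal
  pyroglutamate from Gln/Glu, template-driven tyrosine sulfation and
  disulfide assignment. Peptides render in the field's conventional
  notation (`pQ…a`, `Y(SO3H)`, `+` for truncated ends).
- **Family classification** — an editable, ordered motif library
  (FLRFamide, allatostatin A, leucokinin, pyrokinin, sulfakinin, SIFamide,
  orcokinin, …) plus exact-structure templates; everything else is a
  linker/precursor-related peptide.
- **Receptor characterization** — Kyte–Doolittle hydropathy profiles,
  transmembrane-segment detection, and superfamily calls
  (rhodopsin-like/secretin-like GPCR, kinase-like) by homology label with
  TM-count corroboration.
- **Conservation statistics** — optimal global alignment (BLOSUM62, affine
  gaps 10/0.5), Clustal-style `*`/`:`/`.` conservation symbols, and the
  conventional statistic
  `% identity = n(*) / max(len_a, len_b) × 100`,
  `% similarity = (n(*) + n(:) + n(.)) / max(len_a, len_b) × 100`.
- **Synthetic ground truth** — a generator for precursors, receptors and
  whole transcriptomes with exact truth tables, so every stage is testable
  without downloading anything.

A curated reference set of predicted American lobster (*Homarus
americanus*) neuropeptide structures ships in `inst/extdata/` together
with the default motif library, PTM templates, and Clustal conservation
groups.

## Worked example

Process a myosuppressin-style precursor from raw protein to classified
mature peptides:

```r
library(pepmine)

prot <- paste0("MKRLLLLLLLLLASA",  # signal peptide
               "QDLDHVFLRFG",      # peptide + amidation donor G
               "KR",               # dibasic cleavage site
               "SSPDMESLLE")       # linker peptide
orf  <- list(protein = prot, upstream_stop = TRUE, terminal_stop = TRUE)
prec <- build_precursor(orf, "prepro-myosuppressin", min_len = 20)
prec
#> <precursor> prepro-myosuppressin  [F]  38 aa
#>   signal peptide: [0,15) (heuristic)
#>   MKRLLLLLLLLLASAQDLDHVFLRFGKRSSPDMESLLE

find_cleavage_sites(prec)
#>   pos kind width source low_confidence
#> 1  26   KR     2   rule          FALSE

peps <- process_precursor(prec)
lib  <- read_motif_library()
for (p in peps) cat(render_peptide(p), "->", classify_peptide(p, lib)$family, "\n")
#> pQDLDHVFLRFa -> myosuppressin
#> SSPDMESLLE -> linker
```

The dibasic site is found by rule, the signal peptide by the heuristic;
the excised fragment `QDLDHVFLRFG` loses its glycine to amidation, its
N-terminal glutamine cyclizes to pyroglutamate, and the full-sequence
myosuppressin motif outranks the generic FLRFamide C-terminal motif.

Pairwise conservation of two receptor fragments:

```r
identity_similarity(global_align("MKTAYIAKQR", "MKTAHIARQR"))
#> identity 80.0% / similarity 100.0% (8 identical, 2 similar, longest 10 aa)
```

Pipeline-level entry points (`run_mine`, `run_predict`, `run_receptors`,
`run_align_stats`, `run_simulate`) orchestrate these stages over FASTA
inputs with a validated YAML/list configuration and write TSV/FASTA
reports.

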