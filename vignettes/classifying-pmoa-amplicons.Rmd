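---
title: "Classifying pmoA amplicons: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pmoA amplicons: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmoaclass)
```

## The problem

*pmoA* encodes the β-subunit of particulate methane monooxygenase and is the
standard phylogenetic marker for methanotrophic bacteria. High-throughput
amplicon surveys of *pmoA* need three things that 16S rRNA pipelines do not
directly provide: a gene-specific taxonomy, classifiers trained against it,
and a way to recognize *novel* sequence types — from slightly divergent
genus-level variants to deeply divergent homologs of the wider
copper-containing membrane-bound monooxygenase (CuMMO) family, to plain
contaminants from non-specific PCR.

`pmoaclass` packages that workflow: a curated 54-leaf CuMMO taxonomy, a
naive Bayesian k-mer classifier, a seed-and-extend local aligner with a
translated fallback, lowest-common-ancestor (LCA) assignment over bit-score
margins, a four-tier novelty procedure, cross-sample summaries, and a
synthetic data generator so the whole chain is testable offline.

## The taxonomy

The packaged taxonomy (`pmoa_taxonomy()`) is a rooted hierarchy of 68 nodes:
53 genus-level leaf taxa under `MOB_like` (Type Ia/Ib/Ic for
gammaproteobacterial methanotrophs, Type IIa/IIb for alphaproteobacterial
ones, and pXMO_like for divergent *pmoA*-like clades whose function is
unresolved), plus one `AOB_like` out-group for the betaproteobacterial
ammonia monooxygenase that broad *pmoA* primers co-amplify. Leaves carry the
curated reference-database size (6628 sequences in total) and one
representative accession.

```{r census}
tr <- pmoa_taxonomy()
tr
validate_db_sizes(tr)
```

One transcription note: the printed source table reuses the level code
`0.1.2` for both TypeII and pXMO_like, which cannot both hold in a tree.
Names, not codes, are authoritative, so the packaged table renumbers
pXMO_like and its descendants to the sibling code `0.1.3` while preserving
every name and parent–child relation. Exporters cover the formats the
surrounding tools expect: a Newick tree plus `id → name` map file (the
"alternative taxonomy" dialect of MEGAN-style viewers, identifiers assigned
in depth-first preorder from 0 so output is diffable), mothur-style
training files (`id<TAB>Rank1;…;Leaf;`), and BLAST-style reference FASTA
headers (`accession [Taxon]`).

## Quality filtering

`quality_filter()` applies the standard pyrosequencing-era screen: minimum
length 300 bp, no ambiguous base calls, and no homopolymer run longer than
8 (a run of 9 is rejected — the rule is read literally as "more than
eight"). When several rules fire, the reported reason follows the fixed
priority `length > ambiguity > homopolymer` so rejection accounting is
deterministic. Chimera detection is deliberately out of scope: the pipeline
accepts an externally produced name list (e.g. from uchime) and removes
those reads by id (`remove_by_name()`), mirroring the mothur
`remove.seqs`/accnos convention.

## The naive Bayesian classifier

The classifier is the RDP-style word-matching model. Training uses
presence/absence of each k-mer per sequence (not multiplicity):

- prior: $P(w) = (n(w) + 0.5)/(N + 1)$, where $n(w)$ is the number of
  training sequences containing word $w$ and $N$ the total;
- per-taxon conditional: $P(w \mid G) = (m(w) + P(w))/(M + 1)$, where
  $m(w)$ counts $G$'s sequences containing $w$ and $M = |G|$.

A read is scored by $\sum_{w \in V} \log P(w \mid G)$ over its distinct
k-mers $V$; both orientations are scored and the better one kept, since
amplicons arrive in either sense. Confidence comes from 100 bootstrap draws
of $\lceil |V|/8 \rceil$ k-mers with replacement (the convention of the
adopted implementation; both knobs sit in `nbc_config()`). A leaf's
confidence is its share of draws won; an internal node's confidence is the
sum over its descendant leaves, so confidence is non-increasing from root
to leaf and the root always carries 100%. The reported taxon is the deepest
node on the consensus path reaching the cutoff (default 80%), so a read
from a novel Type Ib lineage is reported as `TypeIb` — "unclassified
Type Ib" in spirit. Defaults are k = 8 and cutoff 80%; ties in any argmax
break lexicographically for determinism.

### The divergent-singleton attractor

A taxon represented by a single, divergent reference (gp23 in the packaged
taxonomy) acts as an attractor for random non-target reads: for a word
unseen in training, $P(w\mid G) = P(w)/(M+1)$, so taxa with small training
sets pay the smallest floor penalty, and among those, chance word matches
are worth most when the matched word is *unique* to the taxon (its prior is
smallest). At k = 10 chance matches all but vanish, singleton taxa tie, and
ties resolve deterministically away from gp23 — so the attraction weakens,
at the price of sensitivity. The package reproduces this as a direction
(more random reads won by the gp23 analogue at k = 8 than k = 10, counting
maximum-posterior leaf winners), not as a magnitude, which would be
database-specific.

## The search engine

The nucleotide engine is seed-and-extend in the megablast mold: a
read/reference pair is considered only if it shares an exact word of 28 nt
on either strand (`word_size`, the megablast minimum); seeded pairs are
then extended to the *optimal* affine-gap local alignment (Gotoh
Smith–Waterman in C++, match +1, mismatch −2, gap open 5, extend 2). Raw
scores become bits via $(\lambda S - \ln K)/\ln 2$ with the published
ungapped Karlin–Altschul parameters for +1/−2 ($\lambda = 1.33$,
$K = 0.621$). Native bit scores are internally comparable — ranking,
margins and thresholds — but not numerically exchangeable with any external
engine's output, which is why every threshold is configuration, and why
externally produced 12-column tabular results can be substituted via
`parse_external_tabular()`. E-values are not computed; the whole procedure
runs on bit scores. Identity is identical columns over alignment columns,
gaps included, the tabular-output convention.

The translated mode mirrors TBLASTX: all six frames of read and reference,
exact 3-residue word seeds (no neighborhood words — a simplification that
costs little at the ~50-bit decision boundary used here), ungapped X-drop
extension under BLOSUM62 ($\lambda = 0.3176$, $K = 0.134$), stop codons
truncating extensions. Its purpose is a single decision: does a read with
no nucleotide hits still look like a CuMMO protein?

## LCA assignment

`assign_lca()` retains every taxon whose bit score is within `top_percent`
(default 5) of the best hit, multiplicatively
($\mathrm{bits} \ge (1 - t/100)\,\mathrm{bits}_{best}$), and assigns the
read to the single retained leaf or to the lowest common ancestor of the
retained taxa. Widening the margin can only move an assignment toward the
root — a property the tests exercise on random hit sets — which is what
makes internal-node assignments interpretable: a read stably assigned at
TypeIIa under a generous margin is evidence for a lineage branching there,
not classifier noise. Reads whose hits all fall below `min_bit_score` are
reported as `low_score`, distinct from seedless `no_hit` reads, because the
novelty procedure treats the two differently.

## Novelty tiers

`tier_reads()` applies four tiers in precedence order, so each read gets
exactly one label:

1. **contaminant / divergent_CuMMO** — reads with an empty nucleotide hit
   set are re-searched in translated mode; ≥ 50 translated bits rescues
   them as highly divergent CuMMO, otherwise they are contaminants.
2. **moderately_divergent** — best nucleotide bits below
   `divergent_flag_max_bits` (default 150). This is flagged regardless of
   LCA depth: a low absolute score is primary evidence of a new clade even
   when a leaf wins the relative comparison.
3. **internal_node_candidate** — the LCA lands on an internal node.
4. **leaf_assigned** — everything else, eligible for conserved-mismatch
   profiling.

Both bit thresholds are calibrated to an engine and scoring scheme; they
are exposed in `novelty_config()` and never hard-coded into logic.

`conserved_mismatches()` formalizes a visual inspection: project each
leaf-assigned read's alignment onto its reference's coordinates and flag
columns where, among ≥ 5 covering reads, the modal read base differs from
the reference and carries ≥ 80% of the coverage. The 0.8/5 defaults are
this package's formalization of a procedure usually done by eye; both are
exposed. Read gap columns do not count as coverage and read insertions
create no columns, so homopolymer indel noise cannot inflate the count.
Many conserved mismatches against the top reference mean the group is a
coherent novel clade nearest to that taxon.

## The synthetic data generator

Because the real 6628-sequence database is not redistributable here, the
package ships a generator instead of data. `mock_reference_db()` evolves a
random 498-nt coding sequence down the packaged taxonomy with
substitutions only, so all references stay positionally aligned. Design
choices, fixed once:

- per-edge substitution rates 16/10/8/6% by depth, leaving sister leaf taxa
  ~11–12% apart (comfortably beyond the > 5% inter-taxon separation the
  taxonomy relies on) and major groups 20–30% apart; gp23 gets an extra
  25% branch, mirroring its divergent-singleton role;
- references per leaf scale with log10 of the curated database size (1 for
  gp23 up to 4 for the largest taxa, 113 sequences in all), replicates at
  ~2% divergence;
- three codon-aligned 24-nt blocks are exempt from substitution below the
  major-group level, emulating the strongly conserved stretches (primer
  sites, functional motifs) real *pmoA* has. Without them, uniformly
  mutated sequences lose all 28-nt words at divergences where real
  sequences demonstrably keep hits, making word seeding unrealistically
  brittle. Uniform read mutation respects the blocks; synonymous mutation
  does not, because that constraint acts on the protein and silent sites
  stay free.

`synth_reads()` emulates amplicons: one shared in-frame window per group
(one primer pair, one region), independently mutated per read. Divergence
models are `uniform` and `synonymous` (third-codon-position changes that
leave the protein untouched — nucleotide identity falls toward ~70% while
translated identity stays ~100%, the signature of a deeply divergent but
genuine homolog). A group sourced at an *internal* node emulates a novel
lineage branching there: its template is a midpoint of references from two
child subtrees, balanced within the read window so reads score similarly
against both sides — the situation that drives LCA assignments to internal
nodes. Planted shared substitutions (the conserved-mismatch ground truth)
are placed identically in every read, away from window edges (local
alignments would trim terminal mismatches) and outside conserved blocks
(novel clades vary at variable positions). Contaminants are i.i.d. uniform
sequence; chimeras join two taxa at a random breakpoint; optional
homopolymer indels perturb existing runs.

`canonical_groups()` fixes the validation conditions: a clean leaf group
(Mcystis, 2%), a simulated novel lineage at TypeIIa (midpoint + 8%), and a
deep synonymous group (USCa, 28% — near the ~32% ceiling a strictly
synonymous model can reach), with contaminants added by fraction.

What passing on synthetic data does *not* show: the generator has no
platform error model beyond optional homopolymer indels, no compositional
bias, no real conserved-site structure beyond the three blocks, and
references are all equal length and gap-free. Results on real amplicons
depend on a real reference database and will be noisier in exactly the
places the generator is clean.

## Numerical and degenerate-input choices

- All randomness flows from explicit integer seeds; fixed seed means
  byte-identical artifacts, including FASTA output and the pipeline's run
  log (which therefore carries no timestamps).
- Argmax ties (NBC taxa, hit ranking) break lexicographically.
- Reads shorter than the k-mer size or containing no valid word are
  "unclassified" with a reason rather than an error; an empty hit set is a
  valid search outcome, not a failure.
- The empty count table, the single-node taxonomy and the empty reference
  database all round-trip through their writers.
- `subsample_counts()` draws without replacement and refuses depths above
  any row sum, naming the offending sample.
- Goodall's distance is not implemented: its published variants are
  mutually incompatible and the source procedure does not pin one down;
  the five unambiguous measures are.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` run: 500 random read/reference
pairs (reads ≤ 120 bp, word size 8) against an exhaustive Smith–Waterman
oracle; 1000 random hit sets for LCA margin stability; 10 generator
replicates of 12 reads per canonical group plus contaminants for tier
recovery; 100 clean reads for Bayesian/LCA agreement; 300 random reads at
k = 8 vs k = 10 for the attractor direction; and a planted-40 group of 8
reads for conserved-mismatch exactness. These sizes were chosen to make the
stochastic checks statistically unambiguous while keeping a full validation
run in minutes on one core.

## Known limitations

- Native bit scores are not numerically comparable to other engines;
  thresholds tuned elsewhere must be re-calibrated (or external tabular
  results used directly).
- The translated search is ungapped; a frameshift inside a homologous read
  splits its HSP and can halve its bits — consistent with how such errors
  degrade translated searches generally, but worth knowing when tiering
  error-rich data.
- The LCA margin is multiplicative in bits; with very short alignments the
  margin window is narrow and assignments become volatile — filter first.
- `min_support`-style post-filters (requiring several reads per node) are
  not implemented; `summarize_assignments()` output makes them trivial to
  apply downstream if wanted.
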