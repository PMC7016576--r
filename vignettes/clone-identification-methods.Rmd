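---
title: "Methods: identifying clones by coupling Sanger tags with CCS reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying clones by coupling Sanger tags with CCS reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetag)
```

This vignette documents the models implemented in `clonetag`, the rationale
for every default parameter, and the deliberate simplifications. The
package addresses a concrete sequencing-logistics problem: after functional
screening of a high-GC genomic library, the positive colonies' plasmids are
pooled and sequenced with long accurate reads (CCS), which are anonymous,
while each colony's own Sanger reads terminate early on the GC-rich
templates and are too short to span an insert — but long enough to serve as
identifying *tags*.

## 1. Sequence model and alignment engine

All sequences are uppercase strings over `{A,C,G,T,N}` with an explicit
linear/circular topology (`dna_seq`). `N` never matches anything in an
alignment, not even another `N`.

The aligner is an affine-gap Smith–Waterman implemented in C++ (a gap of
length $L$ costs `gap_open` $+ L\,\cdot$ `gap_extend`), with a BLASTN-like
default scheme (match $+2$, mismatch $-3$, open $-5$, extend $-2$).
Percent identity is $100 \cdot \text{matches}/\text{columns}$ where columns
include gap positions. Tie-breaks are deterministic (smallest target start,
then query start, then ends), so the whole pipeline is bit-reproducible.
An exact-occurrence fast path returns early when the full query occurs
verbatim in the target; this is provably the DP optimum (only a gapless,
all-match alignment of the whole query can reach score match $\times$
query length, and the DP tie-break selects the earliest occurrence), and
the test suite checks both paths against an independent full-matrix DP
oracle.

Genome back-verification uses a *fitting* (query-global, target-local)
variant rather than a plain local alignment: a local alignment would trim
mutated insert ends and still report 100% identity, whereas the invariant
we want is *identity = 100 exactly when the representative occurs verbatim
in the genome*.

## 2. Library simulation

* **Genome** — i.i.d. bases with $P(G)=P(C)=$ `gc_target`$/200$. The
  default `gc_target = 75.35` is the high-GC regime the pipeline is
  designed for. An i.i.d. genome has no repeats or compositional domains;
  see limitations below.
* **Partial digestion** — every Sau3AI (`GATC`) cut site is cut
  independently with probability `p_cut = 0.1` per digested molecule. A
  bulk partial digest is emulated by digesting additional independent
  molecules until enough fragments are available. At ~75% GC a `GATC`
  site occurs roughly every 450 bp, so realized fragments at
  `p_cut = 0.1` have a mean length in the few-kilobase range.
* **Size selection** — inclusive window, default 1–3000 bp, the
  small-insert regime. The bundled demo uses `min_bp = 200` on the grounds
  that a functional screen only ever recovers inserts long enough to carry
  an expressed determinant.
* **Distinct loci** — `build_library` draws its `n_unique` loci such that
  any two overlap by less than half the shorter fragment. Partial
  digestion freely produces nested fragments of one region; downstream,
  the deduplication rule would merge those into a single group, making the
  generator's own group labels wrong. The constraint keeps the ground
  truth well-defined without touching the digestion model itself.
* **Ligation** — the insert is placed verbatim into the BamHI cut of a
  synthetic 3162 bp pUC118-like vector, in a fair-coin orientation.
  Sticky-end chemistry (`GATC` overhang compatibility between Sau3AI
  fragments and the BamHI site) is abstracted away: plasmid length is
  backbone + insert.
* **Vector** — `default_vector()` builds the backbone deterministically:
  one BamHI cloning site, one HindIII site 400 bp upstream, one XbaI and
  one EcoRI site downstream, 20 bp forward/reverse primer annealing spans
  flanking the cloning site, and *no* other occurrence of any of these
  sites. HindIII therefore single-cuts every recombinant whose insert
  lacks `AAGCTT`, and XbaI/EcoRI cover the exceptions — the situation the
  enzyme-panel selector is built for. All linearization sites are several
  hundred bases away from the cloning site so both vector arms stay intact
  in a linearized read.

## 3. Enzyme panel selection

`min_enzyme_panel` chooses a minimum-cardinality set of enzymes such that
every plasmid is cut *exactly once* by at least one member (a single cut
linearizes a circle without fragmenting it). The search is exact —
subsets enumerated by increasing size — for catalogues up to 20 enzymes,
and greedy set cover with a deterministic tie-break above that. Tests
verify minimality against exhaustive subset enumeration.

## 4. Read simulation

* **CCS** — per-base independent substitutions, insertions and deletions;
  defaults 0.2% each, the circular-consensus accuracy regime. The
  `raw_pacbio` preset (6/5/2%) reflects raw subreads; `perfect` is
  zero-error. The read spans the full linearized plasmid (full-length
  consensus assumption; no coverage or quality modelling).
* **Sanger** — the read starts flush 3' of the primer and terminates at
  base $i$ with hazard $\min(1,\; h_0\,e^{\beta g_i})$, where $g_i$ is the
  GC fraction of the trailing 50 template bases. This is a deliberately
  simple phenomenological stand-in for polymerase stalling and secondary
  structure on GC-rich templates: it produces the two properties that
  matter downstream — read lengths from tens to hundreds of bases, and
  mean length monotonically decreasing in local GC (tested). Defaults
  $h_0 = 5\times10^{-4}$, $\beta = 2$, cap 1000 bp. Reads shorter than
  `min_valid = 20` bp are flagged invalid: ~20 bp is the practical lower
  limit for an identifying tag (a shorter match is not reliably unique).
  Reverse reads are reported in sequencing orientation.

## 5. Identification pipeline

Thresholds live in `identify_config()`:

* **Trimming** (`arm_len = 200`, arm identity ≥ 80%, arm length ≥ 30 bp) —
  both 200 bp backbone arms flanking the cloning site are aligned against
  the read in both orientations; the insert is the segment strictly
  between the inner arm boundaries. Reads failing both arms are
  `vector_not_found`; adjacent arms mean `empty_vector`.
* **Deduplication** (identity ≥ 99%, coverage ≥ 90% of the shorter,
  single linkage) — sibling clones from a partial digest carry identical
  or nested inserts; 99%/90% tolerates CCS-level noise without merging
  distinct loci. Exact and reverse-complement equality shortcut the
  alignment; candidate pairs are prefiltered by shared 15-mers; group ids
  are assigned by the lexicographically smallest member, so output is
  independent of input order (tested).
* **Tag assignment** (identity ≥ 90%, aligned length ≥ 20 bp, margin ≥ 5)
  — each usable tag is aligned on both strands against inserts sharing at
  least one exact 16-mer with it. `k_assign = 16` reflects the skewed
  k-mer background at 75% GC: the per-position match probability between
  unrelated sequences is $\sum_b p_b^2 = 0.3125$, so unrelated
  kilobase-scale inserts routinely share 12-mers, but almost never
  16-mers. The margin is computed against the best insert of any *other*
  duplication group: duplicate inserts of the clone's own group are
  identical by construction and must not count as competitors (a naive
  margin would declare every duplicated clone ambiguous). Forward and
  reverse evidence must agree on the group. Failures degrade per read,
  then per clone (`too_short`, `ambiguous`, `no_hit`) — never fatally.
* **Back-verification** — 15-mer seeds at ~32 positions across the
  representative are matched exactly on both genome strands, clustered by
  diagonal, and the best cluster is extended with a fitting alignment over
  a ±150 bp window. The report carries the 1-based locus, strand,
  identity and GC of every unique representative.

When a ground-truth manifest is available, `run_identification` scores
itself: assignment accuracy over all clones with at least one usable tag,
group-count match, and exact-locus rate.

## 6. ORF scanning

Six-frame prediction with bacterial/archaeal translation table 11. A
complete ORF runs from the first start codon after the previous in-frame
stop to the next stop (stop included in the length, default minimum
150 nt); open reading runs hitting a sequence edge are flagged
`5prime`/`3prime`/`both`. `alt_starts` adds GTG/TTG initiation, rendered
as M. The homology-hit filter keeps rows with E-value < 1e-30 *and*
identity > 30% (both strict) — a deliberately conservative annotation
gate.

## 7. Testing strategy and problem sizes

Every algorithmic component is tested against an independent oracle:
full-matrix DP in plain R for local and fitting alignment scores (plus a
`Biostrings::pairwiseAlignment` cross-check), a one-base-at-a-time
rotation scan for restriction sites, per-frame exhaustive enumeration for
ORFs, and exhaustive subset search for enzyme panels. Exhaustive
alignment verification runs over all sequence pairs up to 5 bp on a
two-letter alphabet plus hundreds of random pairs up to 50 bp; ORF
verification uses 40 random 600 bp sequences. These sizes are the
package's choice: they bound runtime while exercising every code path
(gaps, ties, empty alignments, truncations, wrap-around sites).

The fixture sizes in the acceptance tests (80 kb worked-example genome,
40 kb perfect-recovery genomes, 250 kb / 50-clone noise fixture) are
likewise problem-size choices made for the stated runtime budgets; the
generator parameters themselves (GC target, `p_cut`, size window, error
rates) are study conditions and were not tuned to the tests.

## 8. Known limitations

* The simulated genome is i.i.d.: no repeats, operons, or GC skew, which
  makes genome back-verification easier than on a real genome with
  repeated elements (seed clustering mitigates but does not remove this).
* No chimeric inserts, vector self-ligation, multi-insert ligations, or
  clone cross-contamination.
* CCS reads are always full-length; there is no coverage, quality-score,
  or strand-bias modelling.
* The Sanger hazard model is phenomenological; it reproduces the
  length/GC relationship, not the chromatogram physics.
* Ligation chemistry is abstracted: overhang compatibility is assumed,
  and the insert joins the backbone verbatim.
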