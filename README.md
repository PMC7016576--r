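# clonetag

Identify positive clones from a pooled, high-GC genomic library by coupling
short Sanger "tag" reads with full-length PacBio circular consensus (CCS)
reads — plus a complete, seeded simulator of the wet-lab workflow that the
identification pipeline is validated against.

## The problem

Functional screening of a genomic library (for example, selecting clones
that confer cadmium resistance on a heterologous host) ends with a set of
positive colonies whose plasmids must be sequenced. On templates with very
high GC content (~75%), dideoxy sequencing terminates early: Sanger reads
routinely die after a few dozen to a few hundred bases, too short to span an
insert but long enough to *identify* one. Pooled single-molecule long-read
sequencing of the linearized plasmids yields accurate full-length insert
sequences — but the pool is anonymous, so nobody knows which CCS read came
from which colony.

`clonetag` resolves the anonymity with the short reads each colony *can*
produce:

1. **Vector trimming** — locally align the two backbone arms flanking the
   cloning site against every CCS read (both orientations) and excise the
   insert between them.
2. **Deduplication** — single-linkage grouping of near-identical inserts
   (≥ 99% identity over ≥ 90% of the shorter sequence); partial digestion
   makes sibling clones of the same genomic fragment common.
3. **Tag assignment** — align every usable Sanger tag (≥ 20 bp) against the
   candidate inserts on both strands; a clone is assigned when identity,
   aligned length and the score margin over the best insert of any *other*
   duplication group all clear their thresholds.
4. **Genome back-verification** — seed-and-extend mapping of each unique
   representative onto the source genome, extended with a *fitting*
   alignment so that mutated insert ends count against identity
   (identity is 100 exactly when the insert occurs verbatim).
5. **ORF scanning** — six-frame ORF prediction (≥ 150 nt, bacterial
   translation table 11) on the unique representatives, plus a strict
   post-hoc homology-hit filter (E < 1e-30 and identity > 30%).

The package also contains the full generative counterpart: i.i.d. genome
simulation at a target GC, Sau3AI partial digestion, size selection,
ligation into a synthetic pUC118-like vector, minimal single-cutter enzyme
panel selection for linearization, a CCS error model (substitution /
insertion / deletion), and a GC-dependent early-termination Sanger model.
Because the simulator carries a ground-truth manifest end to end, every
pipeline stage is scored, not eyeballed.

## Quick start

```r
library(clonetag)
report <- demo_run(seed = 42, out_dir = "clonetag_demo",
                   genome_length = 80000)
print(report)
```

The demo builds the 19-clone / 7-group worked example (duplication groups
3, 8, 2, 2, 1, 1, 2) from a simulated 80 kb genome at 75.35% GC, sequences
it at zero error, and recovers the structure exactly:

```
<identification_report> 7 unique group(s) from 19 read(s)
  group_id                    clone_ids ... full_length_bp       locus gc_pct identity_pct
1       u1 x15,x16,x29,x30,x35,x6,x7,x9 ...           2591    973-3563  75.53          100
2       u2                      x40,x41 ...           1122 64210-65331  75.85          100
3       u3                      x13,x28 ...            812 78279-79090  76.60          100
4       u4                    x18,x3,x4 ...            847 54491-55337  74.97          100
5       u5                          x14 ...           1835 42529-44363  75.31          100
6       u6                          x24 ...           1154 34877-36030  74.52          100
7       u7                       x27,x8 ...            972       1-972  75.31          100
scoring: 19/19 clones assigned, accuracy 100.0%, 7 groups (truth 7)
```

`clonetag_demo/` holds every artefact: genome, vector model, plasmids,
truth manifest, enzyme panel, CCS and Sanger FASTA, identification report,
per-clone status, unique representatives, ORF GFF3/proteins, and a
machine-readable scoring table.

Individual stages compose in the obvious way:

```r
genome <- simulate_genome(100000, gc_target = 75.35, seed = 1)
vec    <- default_vector()
lib    <- build_library(genome, vec, n_unique = 5,
                        duplication = c(2, 1, 1, 3, 1), seed = 2)
panel  <- min_enzyme_panel(lapply(lib$clones, `[[`, "plasmid"))
run    <- sim_run(lib$clones, vec, ccs_error_model(), sanger_model(),
                  panel$assignment, seed = 3)
ident  <- run_identification(run$ccs, run$sanger, vec,
                             genome = genome, truth = run$manifest)
ident$report
```

## Command line

A thin Rscript front end lives at `exec/clonetag`:

```
clonetag simulate-genome --length 100000 --gc 75.35 --seed 1 --out genome.fasta
clonetag build-library   --genome genome.fasta --out lib/
clonetag select-enzymes  --plasmids lib/plasmids.fasta --out panel/
clonetag simulate-reads  --library lib/ --out reads/
clonetag identify        --ccs reads/ccs_reads.fasta --sanger reads/sanger_reads.fasta \
                         --vector lib/vector.fasta --vector-annot lib/vector_features.tsv \
                         --genome genome.fasta --out ident/
clonetag orfs            --fasta ident/unique_representatives.fasta --out orfs/
clonetag demo            --seed 42 --out demo/
```

Exit status is 0 on success, 1 on usage errors, 2 on data errors.

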