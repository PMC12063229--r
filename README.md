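# replifork

Single-molecule DNA replication dynamics from nanopore BrdU incorporation
tracks.

## The problem

Where does DNA replication start? In human cells, population-level assays
(Ok-seq, Pu-seq, optical replication mapping) resolve only broad initiation
zones, because they average over millions of cells. Labelling cells with
the thymidine analog BrdU and sequencing ultra-long nanopore reads changes
the game: a base caller assigns every thymidine on every read a probability
of actually being BrdU, and if the BrdU concentration in the medium is
stepped up during labelling (0.5 µM every 2.5 min up to 12 µM, then held),
DNA synthesized later carries more BrdU. Each replication fork therefore
writes its own travel direction onto the molecule as a gradient of BrdU
incorporation, and a single read can reveal fork direction, initiation
events (divergent fork pairs) and termination events (convergent pairs) —
including the dispersed, individually-rare initiation sites that population
methods average away.

`replifork` is for computational biologists who have per-thymidine BrdU
probability tracks (DNAscent-detect-style text files) and want fork,
initiation and termination calls with calibrated enrichment statistics —
plus a forward simulator that makes the whole pipeline testable without any
sequencing data.

## The method

For each read, the fraction of BrdU calls (probability ≥ 0.5) is computed
in consecutive independent windows of 290 thymidines (≈1 kb). Reads with
≥ 5 % BrdU overall are nascent. The noisy window series *y* (percent scale)
is differentiated by total-variation regularized numerical differentiation:
the derivative *u* minimizes

    α·TV(u) + ½‖A u − (y − y₁)‖²

with *A* the trapezoidal antiderivative operator, solved by
lagged-diffusivity fixed-point iteration. Maximal runs with *u* > +1
(percent per window) are rightward forks, runs with *u* < −1 leftward
forks; adjacent divergent/convergent fork pairs define initiation and
termination sites whose inter-fork gap is the site's resolution (sites
< 5 kb are "high-resolution").

On top of the calls:

* **RIGR** — replication initiations per gigabase of mapped reads, with a
  read-constrained permutation null (sites shuffled inside subsampled read
  footprints, 1000 randomizations),
* **relative distance** — colocalization of sites with a region set
  (*d* ∈ [0, 0.5], flat under independence),
* **RFD ensembles** — per-bin (right − left)/total fork directionality
  with direction-randomization bands,
* **fork/transcription co-directionality** at TSS/TES anchors, and
  **meta-profiles** of any bedGraph signal around sites.

The simulator generates asynchronous S-phase molecules with focused
initiation zones plus a dispersed background, constant-speed bidirectional
forks, concentration-dependent incorporation calibrated to the observed
35 %/65 % modal incorporation at 1.5/10 µM, and bimodal per-thymidine
probability emission with a 0.1 % false-positive rate — together with full
ground truth for recovery testing.

## Worked example

```r
library(replifork)

genome <- genome_model(
  data.frame(name = "chr1", length = 1e7),
  focused_zones = data.frame(chrom = "chr1", start = 4.5e6, end = 4.53e6,
                             firing_prob = 0.8),
  dispersed_rate = 1e-5, fork_speed = 1500)

sim   <- simulate_reads(genome, n_reads = 40, read_length = 150000,
                        seed = 11, phase = "labelling",
                        s_phase_duration = 60)
calls <- call_reads(sim$reads)
calls$calls[[1]]
#> <read_calls> sim_read_0002: 2 forks, 1 initiations, 0 terminations

hi <- filter_high_resolution(calls$initiations)
# 21 forks, 6 initiation sites (2 at <5 kb resolution), 4 terminations

cmp <- compare_to_truth(calls, sim$truths, label_schedule())
cmp$recovery_rate        # 1     — every resolvable planted event recovered
cmp$median_error_bp      # 215   — bp from called site midpoint to true origin
```

20 of the 40 simulated molecules are nascent (the rest are unlabelled
template strands or pre-replicated DNA); among planted initiations whose
flanking forks carry a resolvable gradient, all are recovered with ~0.2 kb
localization error.

The ensemble fork-direction statistic on a printed worked example — 5
leftward and 6 rightward forks at one locus:

```r
aff2 <- rfd_ensemble(data.frame(
  read_id = paste0("r", 1:11), chrom = "chrX", start = 0, end = 1000,
  direction = c(rep("left", 5), rep("right", 6))), bin_size = 1000)
round(aff2$rfd, 2)
#> [1] 0.09
```

A thin command-line wrapper ships in `inst/scripts/replifork`
(`simulate`, `windows`, `callforks`, `rigr`, `rfd` subcommands).

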