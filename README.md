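# nanodemux

Demultiplexing of barcoded Oxford Nanopore long reads, built for the reads
that stock demultiplexers give up on. Multiplexed nanopore runs tag each
library with a short barcode (24 nt in the rapid kits) sequenced near the
read start; sequencing errors — mostly short insertions and deletions — push
many reads into the "unclassified" bin. `nanodemux` assigns reads by local
alignment of every barcode against the read start, with explicit guards
against false assignment, and ships a seeded read simulator and an
evaluation harness so the whole pipeline is testable without any sequencing
data.

## Method

For a read *r* and barcode set *B*, each barcode is aligned against the
first 110 nt of *r* by Smith–Waterman local alignment with linear gaps
(match +1, mismatch −1, gap −1, optionally a non-linear bonus per run of ≥ 4
consecutive matches). Ranking the per-barcode best scores *S₁ ≥ S₂ ≥ …*,
the read is assigned to the top barcode iff

- *S₁* ≥ 13 (score floor: more than half an intact barcode),
- *S₁* − *S₂* ≥ 2 (margin over the best *other* barcode), and
- the winning alignment starts inside a score-tiered window around the
  expected barcode position (~47): start ∈ [36, 51] for score 13,
  [30, 75] for score 14, [5, 85] for ≥ 15.

Otherwise the read is unclassified, with a machine-readable reason. Reads
shorter than 550 nt are set aside before any alignment. Assigned reads are
trimmed after the barcode and written per barcode (trimmed + untrimmed QC
copies), alongside unclassified/too-short FASTQs and a summary table.

## Worked example

Simulate 240 reads at 2% substitution/insertion/deletion rates, demultiplex
them against the bundled 24-barcode set, and score against the generator's
truth:

```r
library(nanodemux)
sim <- simulate_reads(sim_params(n_reads = 240, p_sub = 0.02, p_ins = 0.02,
                                 p_del = 0.02, seed = 7))
run <- demux(sim$reads, "builtin24", demux_config(), out_dir = "demo_out")
print(run)
#> demux run: 240 reads, 24 barcodes
#>   assigned:         240 (100.00%)
#>   unclassified:        0 (0.00%)
#>   too_short:          0 (0.00%)
#>   outputs in: demo_out
head(run$summary, 3)
#>   label n_reads   fraction total_bases mean_length mean_quality
#> 1  BC01      10 0.04166667       10325      1032.5           12
#> 2  BC02      10 0.04166667       10317      1031.7           12
#> 3  BC03      10 0.04166667       10297      1029.7           12
score_against_truth(run, sim$truth)
#> evaluation over 240 reads (0 too short):
#>   classified: 240 (100%)
#>   correct:    240 (100%)
```

Every read was assigned, and to the right barcode: at 2% error rates a
24-nt barcode still typically scores ~20, far above the floor of 13 and the
runner-up. The summary's `mean_length` is the length of the *trimmed*
output (leader + barcode + flank removed from ~1,100-nt simulated reads);
`mean_quality` is the Phred of the mean per-base error probability. Single
alignments can be inspected directly:

```r
local_align(load_barcode_set("builtin24")$sequence[1], sim$reads$sequence[1])
#> local alignment: score 24, read 46-69, barcode 1-24
#>   MMMMMMMMMMMMMMMMMMMMMMMM
```

(Here an upstream deletion shifted the barcode one base left of its
error-free position 47 — comfortably inside the [5, 85] window for a
score-24 alignment.)

The bundled barcode FASTAs are synthetic, separation-screened stand-ins
(`inst/extdata/*_synthetic.fasta`); point `--barcodes`/`barcodes` at a
FASTA of your kit's sequences for real data.

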