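# prc2scan

Tools for studying how Polycomb repressive complex 2 (PRC2) localizes to
large GC-rich DNA elements that lack activating transcription-factor
motifs.

In ES cells, PRC2 (via its Ezh2 subunit) deposits the repressive mark
H3K27me3 mostly at CpG islands, typically alongside the activating mark
H3K4me3 ("bivalent" promoters). A compact sequence model explains much of
this landscape: **any sufficiently large GC-rich element — even one taken
from a prokaryotic genome — recruits PRC2, provided it is depleted of
activating motifs (AMs) and transcriptionally silent.** Testing that model
computationally requires a specific toolbox, which this package provides:

* **Sequence scans** — sliding-window GC fraction and CpG
  observed/expected (`O/E = N_CpG · L / (N_C · N_G)`), CpG-island calling
  (GC ≥ 0.50, O/E ≥ 0.60, ≥ 200 bp by default), and discovery of GC-rich,
  AM-depleted 1 kb elements in arbitrary genomes
  (`scan_windows`, `call_cpg_islands`, `find_gc_rich_elements`).
* **Motif scanning** — PWM matches with exact score-distribution
  per-position p-values (α = 5×10⁻⁵ convention), motif counting,
  half-island clustering asymmetry with a two-sided binomial test, and
  depletion flags (`scan_pwm`, `score_distribution`, `asymmetry_score`).
* **ChIP-Seq enrichment** — read-density tracks, an empirical null built
  from randomized reads matched to each dataset's depth, sliding 1 kb
  window calling at p < 10⁻³, merging of enriched windows within 1 kb,
  promoter mark classification / bivalency / Venn counts, width-sorted
  heat-map matrices, and spreading-extent measurement
  (`build_null`, `call_enriched_windows`, `merge_regions`,
  `classify_promoters`, `signal_matrix`, `spreading_extent`).
* **Expression & methylation** — HCP/ICP/LCP promoter CpG classes,
  max-1-kb exonic RNA-Seq scores, Ezh2-vs-expression stratification of
  inactive HCPs, TSS methylation composites
  (`classify_promoter_cpg`, `expression_score`, `stratify_inactive_hcps`,
  `methylation_composite`).
* **ChIP-qPCR** — fold enrichment from quantities or Ct values,
  negative-control normalization, replicate mean ± SEM (`qpcr_analyze`).
* **Synthetic data** — seeded generators (first-order Markov genomes with
  controllable GC *and* CpG O/E, planted motifs, planted ChIP enrichment,
  RNA-Seq, binomial methylation, noisy qPCR) with ground-truth records,
  plus four ready-made presets (`generate_genome`, `generate_reads`,
  `simulate_preset`).

See `vignettes/prc2scan-methods.Rmd` for the full methods account.

## Worked example: the prokaryote selection loop

Simulate a 100 kb low-GC genome carrying two GC-rich 1 kb plants (one
laden with activating motifs), scan for AMs, and ask for island-criteria
windows containing ≤ 2 hits:

```r
library(prc2scan)

sim      <- simulate_preset("ecoli-like", seed = 42)
hits     <- scan_pwm(sim$genome, sim$pwms$AM, alpha = 5e-5)
elements <- find_gc_rich_elements(sim$genome, hits, max_hits_per_window = 2)
elements
#>       contig start   end strand gc_fraction    cpg_oe n_hits
#> 1 ecoli_frag 30000 31000      *       0.636 0.8606363      0
```

Exactly one element comes back: the motif-free plant at 30,000 (63.6% GC,
CpG O/E 0.86, zero AM hits). The second plant — same GC content but six
planted motifs — is rejected, which is the entire point of the selection.
Both plants are visible to the plain island caller:

```r
call_cpg_islands(sim$genome)
#>       contig start   end strand gc_fraction    cpg_oe length_bp
#> 1 ecoli_frag 29870 31096      *   0.5889070 0.8575667      1226
#> 2 ecoli_frag 69945 71083      *   0.6221441 0.8267972      1138
```

Add ChIP: simulate an Ezh2 read set 10-fold enriched over the element and
call enrichment against the randomized-read null:

```r
gl    <- genome_lengths(sim$genome)
reads <- generate_reads(chip_spec(2000, regions = data.frame(
           contig = "ecoli_frag", start = 30000L, end = 31000L, fold = 10),
           label = "Ezh2"), gl, seed = 43)
merge_regions(call_enriched_windows(reads$reads, gl, seed = 44))
#>       contig start   end strand     p_value width_bp summit n_windows
#> 1 ecoli_frag 29200 31800      * 0.000999001 2600     30500  9
```

One merged region over the plant, summit at 30,500 (the element
midpoint), minimum window p = 1/1001 — the floor of a null pooling 10
randomizations, i.e. "stronger than anything the randomized background
produced".

## Command line

```sh
prc2scan simulate --preset ecoli-like --seed 1 --outdir sim/
prc2scan scan-islands --fasta sim/genome.fa --out islands.bed
prc2scan find-elements --fasta sim/genome.fa --pwm sim/motifs.pwm \
         --alpha 5e-5 --window 1000 --max-hits 2 --out elements.bed
prc2scan call-enrichment --reads reads.bed --fasta sim/genome.fa \
         --window 1000 --pthresh 1e-3 --merge-gap 1000 --seed 7 \
         --out regions.bed
```

Every run writes a JSON log (seed, config snapshot, input digests) beside
its output — the randomized null makes seed capture mandatory.

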