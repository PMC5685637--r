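# itss — internal transcription start sites from RNA-seq coverage

`itss` finds transcription start sites that appear *inside* annotated open
reading frames when a test condition is compared with a control — the
signature of condition-specific 5'-truncated transcripts, such as those
induced during yeast mid-sporulation by Ndt80 through middle sporulation
elements (MSEs) buried in coding sequence. The input is per-base coverage
(bedGraph) for one control and ≥ 2 test samples, a GFF3 annotation, the
genome FASTA, and optionally a BED of contaminant features to mask and
JASPAR-style motif matrices.

## Method

For each test sample *t* against the control *c*:

1. coverage is smoothed with a Gaussian kernel (σ = 50 nt, central 99.5%
   mass) and normalized to the sample's total coverage;
2. the shape difference is computed in 150-nt windows every 5 nt as the
   RMSD between the two area-normalized curves,
   RMSD(w) = √( mean over w of (cᵢ/Σc − tᵢ/Σt)² ),
   which responds to transcript boundaries but not to uniform induction;
3. RMSD peaks are filtered: TES-like peaks (more test coverage in the
   5' flank than the 3' flank, in transcription orientation) are removed,
   then three strict criteria apply at the peak — RMSD > median of all
   windows; smoothed c+t coverage strictly between its median and 95th
   percentile; smoothed t−c difference > its 90th percentile;
4. each surviving peak grows into a transcript contig: positions are
   scanned outward while t−c stays ≥ the 90th percentile; nearby contigs
   (5' ends < 1 kb apart, averaged differences within 3-fold) are merged;
   contigs are scored (averaged difference × size) and ranked;
5. contigs found in ≥ 2 samples (span ≤ 4 kb) become consensus calls with
   an averaged rank, a mean TSS and a ±range; a call is **internal** when
   its TSS lies ≥ 75 nt from both codons of an ORF and its averaged rank
   is ≤ 800;
6. the 300 nt upstream of each call's 3'-most possible TSS are scanned
   with a position weight matrix (sites scoring > 85% of the possible
   score range, both strands), and gene-level enrichment against all
   ORF-upstream windows is tested with a two-sided Fisher exact test.

A synthetic-data module generates toy genomes with planted internal TSSs,
TES-shift decoys, planted promoter motifs and negative-binomial noise, so
the whole pipeline is testable without downloads.

## Worked example

```r
library(itss)

spec <- sim_spec(seed = 20, chrom_count = 2, genes_per_chrom = 15,
                 induced_count = 4, test_samples = 3)
sim <- simulate_dataset(spec)

cfg <- default_config(
  genome = sim$paths$genome, annotation = sim$paths$annotation,
  exclusions = sim$paths$exclusions, control = sim$paths$control,
  tests = sim$paths$tests,
  motifs = list(MSE = system.file("extdata", "mse_synthetic.pfm",
                                  package = "itss")))
run <- run_pipeline(cfg)
print(run)
#> <itss_run>
#>   test_1: 946 peaks -> 782 after TES filter -> 13 after criteria -> 10 contigs
#>   test_2: 948 peaks -> 780 after TES filter -> 13 after criteria -> 9 contigs
#>   test_3: 952 peaks -> 759 after TES filter -> 10 after criteria -> 8 contigs
#>   consensus: 4 calls; internal: 4
#>   MSE: 4/4 foreground vs 1/30 background, p = 0.000108

run$internal[, c("gene_id", "offset", "tss_range", "avg_rank", "support", "mse_hit")]
#>   gene_id offset tss_range avg_rank support mse_hit
#> 1   G0020   1178         2        1       3    TRUE
#> 2   G0026   1723         4        2       3    TRUE
#> 3   G0005    314         1        3       3    TRUE
#> 4   G0010    456        19        4       3    TRUE
```

All four planted genes are recovered with 3-sample support; `offset` is
the called TSS relative to the first ORF base (`+offset±range` in the TSV
report) and every call's upstream window contains the planted MSE.
Scoring against the ground truth:

```r
score_against_truth(run$internal, sim$truth)
#> precision 0.75, recall 0.75, mean |TSS error| 87 nt   (±100 nt tolerance)
```

The called TSS sits ~85–95 nt upstream of the true start — an intrinsic
property of defining the TSS as the contig boundary of a σ = 50 nt
smoothed difference (see the methods vignette), so one of the four calls
falls just outside the ±100 nt tolerance here.

With `outdir` set, the pipeline writes per-sample contig tables, the
internal-TSS report (`internal_tss.tsv`), a consensus BED,
stage-count logs, enrichment JSON and run metadata with input checksums.
A thin CLI over the same functions lives at `inst/cli/itss.R`
(`itss.R simulate|scan|call|motif|run -c config.yaml`).

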