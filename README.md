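# barcodekit

Multi-locus DNA-barcoding analysis for biodiversity surveys: quality
screening, distance-based tree building, barcode-gap OTU delimitation,
cross-marker consensus, reference matching and mitochondrial pseudogene
screening — with a synthetic two-marker data generator so every stage is
testable against known species truth.

## The problem and who this is for

Barcoding surveys sequence short standardized fragments — typically
cytochrome c oxidase subunit I (COI, ~658 bp, protein-coding) and
mitochondrial 16S rRNA — for hundreds of specimens, then ask: how many
species-like clusters (operational taxonomic units, OTUs) are present, do
they match the morphological identifications, which are new to the reference
databases, and could any sequences be nuclear pseudogene copies (NUMTs)
rather than genuine mitochondrial barcodes?  `barcodekit` packages that
entire chain for R users who want it reproducible, scriptable and tested.

## The methods at its core

* **Distances**: p, Jukes–Cantor `d = -(3/4)·ln(1 − (4/3)p)` and Kimura
  two-parameter `d = -(1/2)·ln(1 − 2P − Q) − (1/4)·ln(1 − 2Q)` with pairwise
  deletion of gaps and ambiguities.
* **Trees**: BIONJ (variance-weighted neighbour joining) with Felsenstein
  nonparametric bootstrap supports.
* **OTU delimitation**: Automatic Barcode Gap Discovery — rank all pairwise
  distances, find the first gap that both ends beyond a prior maximal
  intraspecific divergence *P* and is wider than `x · max(local mean gap, P)`,
  split by single linkage below the gap, recurse within groups, scan a
  geometric series of priors (COI: 0.001–0.1, x = 1.125, 10 steps; 16S:
  0.001–0.05, x = 1.5) and keep the modal partition.
* **Consensus**: where markers disagree, the finer grouping stands only if
  each extra group diverges by ≥ 0.05 substitutions/site in COI or ≥ 0.03 in
  16S; otherwise the option with fewer OTUs wins.
* **Novelty**: identity to a local reference library by global ends-free
  alignment; COI known above 95%, 16S above 97%; >95% identity to a
  non-target reference flags contamination.
* **Pseudogene screen**: in-frame stops and frameshifts under the
  invertebrate mitochondrial code (table 5), divergent translations, GC%
  outliers (|z| > 3), and the cross-marker GC correlation.

See `vignettes/barcodekit-methods.Rmd` for the full account.

## Worked example

Simulate a 6-species, 4-specimens-per-species two-marker survey, write it to
disk, and run the full pipeline on the files:

```r
library(barcodekit)

ds    <- generate_dataset(sim_config(n_species = 6, seqs_per_species = 4, seed = 42))
paths <- write_dataset(ds, "survey")
cfg   <- pipeline_config(coi_fasta = paths[["coi_fasta"]],  coi_fastq  = paths[["coi_fastq"]],
                         r16s_fasta = paths[["r16s_fasta"]], r16s_fastq = paths[["r16s_fastq"]],
                         metadata = paths[["metadata"]], out_dir = "survey/out",
                         n_boot = 50, seed = 42)
res <- run_pipeline(cfg)
str(res$counts)
```

```
List of 11
 $ n_otus_coi           : int 6
 $ n_otus_16s           : int 6
 $ n_otus_consensus     : int 6
 $ n_new_coi            : int NA
 $ n_new_16s            : int NA
 $ n_multi_name_otus    : int 0
 $ n_single_name_otus   : int 6
 $ n_split_morphospecies: int 0
 $ n_conflicts          : int 0
 $ n_dropped_qc         : int 0
 $ n_contaminants       : int 0
```

Both markers and their consensus recover the 6 simulated species exactly;
every OTU carries a single morphospecies name, nothing was dropped by the
Phred/length screen, and no cross-marker conflicts arose.  The novelty
columns are `NA` because no reference library was configured.  The per-OTU
table mirrors the summary tables such surveys publish:

```r
head(res$otu_summary)
```

```
  otu_id         morphospecies n_individuals coi_new r16s_new
1 SP0001 Synthetica simulata01             4      NA       NA
2 SP0005 Synthetica simulata02             4      NA       NA
3 SP0009 Synthetica simulata03             4      NA       NA
...
```

and the pseudogene screen reports per-sequence flags plus cohort GC
statistics:

```r
res$pseudogene
#> pseudogene_report: 24 sequences screened, 0 flagged; GC% range 39.09-41.53; ...
```

`survey/out/` now holds the QC drop log, PHYLIP distance matrices, Newick
trees with bootstrap labels, per-prior partitions, the consensus partition,
conflict log, pseudogene report, OTU summary and a `manifest.json` recording
every parameter and the seed; reruns with the same inputs and seed are
byte-identical.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/barcodekit simulate --out sim --n-species 20 --seed 1
Rscript inst/exec/barcodekit all --coi-fasta sim/coi.fasta --r16s-fasta sim/r16s.fasta \
        --metadata sim/metadata.tsv --out sim/out --seed 1
```

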