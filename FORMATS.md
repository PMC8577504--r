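# File formats

All interchange files are tab-separated text with a header row; `NA` encodes
missing values.  Genomic coordinates are 1-based throughout (annotation and
VCF).  Genotype calls use the alphabet `AA`, `AB`, `BB`, `NoCall`, with the
A allele being the reference/major allele; contrast is positive toward `AA`.

## Inputs

### intensities.tsv (IntensitySet)
| column | type | meaning |
|---|---|---|
| probeset_id | string | probeset (variant) identifier |
| probe_replicate_index | int | 1-based replicate probe index within the probeset |
| sample_id | string | sample identifier |
| channel_A | double | raw linear A-channel intensity (>= 0) |
| channel_B | double | raw linear B-channel intensity (>= 0) |

### annotation.tsv (ProbesetAnnotation)
`probeset_id`, `rsid`, `chrom`, `pos` (1-based), `ref_allele`, `alt_allele`,
`n_replicate_probes`, `panel` (disease panel name or `NA`).

### manifest.tsv
`sample_id`, `plate_id`, `batch_id`.  A batch groups plates processed
together (24 per batch in production); it is the unit of cluster fitting.

### ref_maf.tsv
`variant_id`, `ref_maf` — reference (sequencing-cohort) minor-allele
frequency as a fraction.

### panels.tsv (optional; defaults to the annotation's `panel` column)
`panel`, `variant_id`.

### gold_standard.tsv (optional; synthetic runs use truth/genotypes.tsv)
`sample_id`, `variant_id`, `confirmed_genotype` (AA/AB/BB).

## Stage outputs

### calls_base.tsv / calls_rarehet.tsv / calls_advnorm.tsv / calls_final.tsv (GenotypeMatrix)
`probeset_id`, `sample_id`, `call`, `confidence` (posterior of the chosen
cluster, `NA` for non-converged probesets), `provenance`
(`original`/`rarehet`/`advnorm`/`conflict`).

### cluster_model.tsv
`probeset_id`, `batch_id`, `cluster` (AA/AB/BB), `mean`, `var`, `weight`,
`n_soft` (soft-assigned sample count), `converged` — one Gaussian mixture
component per row, in contrast units.

### rarehet_decisions.tsv
`probeset_id`, `sample_id`, `dispersion` (max absolute deviation of a
replicate contrast from the replicate median), `all_replicates_ab`,
`verdict` (`keep`/`demote_to_nocall`).

### plate_shifts.tsv
`probeset_id`, `batch_id`, `plate_id`, `n_samples`, `delta` (estimated
contrast shift; `NA` when skipped), `flagged`, `skipped`.

### advnorm_audit.tsv
`probeset_id`, `sample_id`, `plate_id`, `delta`, `old_call`, `new_call`.

### concordance.tsv (ConcordanceResult)
`variant_id`, `array_maf`, `n_called`, `undefined`, `ref_maf`, `log2_ratio`
(log2(array/ref); `NA` when either MAF is 0), `verdict`
(`retained`/`excluded`/`indeterminate`), `t_upper`, `t_lower`.

### concordance_bins.tsv
`bin` (reference-MAF bin), `n`, `n_excluded`, `exclusion_rate`.

### worklist.tsv
`panel`, `variant_id`, `sample_id`, `call` — every minor-allele call
requiring wet-lab confirmation.

### screening_report.tsv (ScreeningReport)
`panel`, `bin` (`0.01%<MAF<=1%` / `MAF<=0.01%`), `TP`, `FP`, `TN`, `FN`,
`ppv`, `npv` (percentages, half-up to 2 decimals, `NA` when the denominator
is zero).

### calls_final.vcf
VCF 4.2; one record per variant; `GT` per sample with NoCall as `./.`;
per-sample FORMAT field `PV` carries the adjustment provenance.

### run_manifest.json / resolved_config.yaml / report.json
Run provenance: package version, seed, input MD5 digests; the resolved
pipeline configuration; adjustment and concordance summaries.

## Truth tables (simulation only, under `truth/`)
`genotypes.tsv` (`probeset_id`, `sample_id`, `genotype`),
`probesets.tsv` (`probeset_id`, `true_maf`, `cross_hyb`, `cross_hyb_maf`),
`artifacts.tsv` (cell, replicate, channel, multiplicative factor),
`shifted_plates.tsv` (`plate_id`, `shift`, `channel`).
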