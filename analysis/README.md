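# Analysis workflow

Numbered drivers over the `phemr` package, run from the repository root:

```sh
Rscript analysis/01_simulate_inputs.R      # synthetic study inputs + truth
Rscript analysis/02_phewas_enrichment.R    # prune -> match -> enrich
Rscript analysis/03_mr_phewas.R            # phenome-wide IVW screen
Rscript analysis/04_bidirectional_mr.R     # bidirectional estimator panels
Rscript analysis/05_colocalization.R       # regional coloc + F statistics
```

Each stage reads `analysis/data/synthetic/` (written by stage 1) and writes
its tables under `results/`. An optional integer seed may be passed as the
first argument to stages 1, 2 and 4 (default 2026); stages 3 and 5 are
deterministic given their inputs.

## Running on real summary statistics

The same stages run on real inputs by replacing the files under
`analysis/data/` with downloaded tables in the canonical dialect
(`SNP CHR POS EA OA EAF BETA SE P N`, tab-separated; use the `column_map`
argument of `read_gwas_table()` for other dialects). For the published
bidirectional analysis the expected layout is:

```
analysis/data/accessions/
  pbc.tsv                 # Open GWAS ebi-a-GCST003129
  hypothyroidism.tsv      # Open GWAS ebi-a-GCST90029022
  finngen_hypothyroidism.tsv  # finn-b-hypothyroidism (replication)
  pbc_ld.tsv              # LD matrices from the 1000 Genomes EUR panel
  hypothyroidism_ld.tsv
  eqtl_<gene>.tsv         # eQTLGen whole-blood cis-eQTLs per gene region
```

These files are not redistributed here; the reproduction check in the test
suite fails until they are supplied.
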