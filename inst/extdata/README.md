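# Packaged fixtures

## table1_assays.csv

A transcription of the published catalog of pyrosequencing methylation assays
covering the known human imprinted loci: one row per assay with its genomic
placement (original genome build, coordinates kept as opaque 1-based
positions), parent-of-origin methylation mark, germ-line/somatic timing
('#'-suffixed germ-line rows mark the qualified entries), average somatic
methylation (%), location category, CpG-island flag, CTCF occupancy class
(Y = constitutive across cell lines, YV = variable, N = none) and CpG density
(CpGs per 100 bp over a 500 bp window; every value is a multiple of 0.2).

Known discrepancy, kept as printed: the source text describes 50 assays but
the printed catalog lists 49 rows; the identity of the missing row is
unresolved and the table is shipped as transcribed rather than patched.

`cluster_id` is package-supplied annotation, not a printed column: assays are
grouped into the well-known imprinted clusters by chromosome and position
proximity (DIRAS3, IGF2R, MEST, GRB10, PEG10/PON1, IGF2/H19, KCNQ1,
DLK1-MEG3, PWS/AS, PEG3, NNAT/BLCAP, GNAS). Singleton assays have an empty
cluster_id.
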