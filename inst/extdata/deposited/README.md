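Drop-in location for the six processed chromatogram matrices (three
replicates x two isotope channels), named r1_medium.tsv, r1_heavy.tsv,
r2_medium.tsv, r2_heavy.tsv, r3_medium.tsv, r3_heavy.tsv, in the TSV
layout of writeChromatogramMatrix(): header row, first column `protein`,
one column per fraction in elution order, empty cells for missing
quantifications. The matrices are not redistributed with the package; the
outlier-removal acceptance check runs against them when present.
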