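# extdata

`rpalmatum_highlow_counts.tsv` — pooled codon counts of the top- and
bottom-5%-CAI gene sets from a published *Rheum palmatum* transcriptome
codon-usage analysis, as a worked example for the optimal-codon procedure
(`read_codon_counts()` + `pooled_rscu_table()` + `optimal_codon_test()`).

Rows marked `source = inferred` (Asp GAC and the Gly remainder) are absent
from the published table; their family totals were reconstructed from the
published RSCU values (`family total = k * N / RSCU`, rounded) so that the
printed codons GAU and GGU can be tested against their family rest. The
reconstruction reproduces the published RSCU of GAU (1.52 high / 0.70 low)
and GGU (1.30 / 0.53). The Gly remainder is split evenly across
GGC/GGA/GGG: the split cannot change any test of a printed codon, and the
even split itself cannot be flagged optimal (its high-pool share is below
its low-pool share). Glu is absent from the published table and is left
absent here.
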