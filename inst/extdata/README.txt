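synthetic_supplementary_targets_{AOyne,PZyne}.txt

Synthetic stand-in accession lists for the per-probe high-confidence
candidate-target sets of a two-probe competitive chemoproteomic screen.
The set sizes (24 and 16 candidates, 9 shared) match the published
screen; the accessions themselves are synthetic placeholders (SYN*
prefixes), since the deposited candidate lists are not redistributed
here. They exist to exercise list-based set intersection
(intersect_probes) against the published counts.
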