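# Synthetic CSX-style assay definition. The reference sequence is invented;
# site coordinates follow the published assay geometry (1-based, within the
# inner amplicon). The third control position is listed twice in the source
# material; the reader deduplicates it with a warning.
name: CSX-synthetic
coordinate_base: 1
cpg_positions: [2, 4, 6, 18, 22, 37, 40, 51]
control_positions: [14, 20, 14]
primer_fwd: GGGGAGAAGGGGTTTTTAATAT
primer_rev: AAAAACACTCCTAAAAAAACAACTAA
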