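{
  "name": "hb-MS2-synthetic",
  "comment": "Synthetic stand-in for a gap-gene MS2 reporter; per-construct loop coordinates are not published. 24 loops at 54-bp spacing starting 600 bp downstream of the TSS on a 4.5-kb transcription unit.",
  "gene_length_bp": 4500,
  "loop_ends_bp": [654, 708, 762, 816, 870, 924, 978, 1032, 1086, 1140, 1194, 1248, 1302, 1356, 1410, 1464, 1518, 1572, 1626, 1680, 1734, 1788, 1842, 1896],
  "elongation_rate_kb_per_min": 1.8
}
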