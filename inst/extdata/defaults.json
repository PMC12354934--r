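{
  "quality_standard": 0.8,
  "n_tiles": 24,
  "n_sections": 30,
  "t_trad_s": 144,
  "t_fast_s": 14.4,
  "t_slow_s": 144,
  "t_compute_s": 28.8,
  "t_tile_s": 4,
  "t_section_s": 20,
  "steepness_k": 4,
  "seed": 1
}
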