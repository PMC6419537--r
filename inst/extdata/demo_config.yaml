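# Demonstration run: two replicate populations at two release times,
# quantified and summarized end to end.
seed: 1
out_dir: "ciliarrival_demo"
stages: [simulate, quantify, timecourse, slopes]
channel_map:
  gfp: gfp
  surface: surface
  cilium: cilium
simulate:
  n_cells: 8
  times: [0.5, 1.0]
  replicates: 2
  stained_side: [apical, basolateral]
  profile: population
  kinetics:
    k_release: 2.0
    phi_bl: 0.62
    k_transcytosis: 0.5
    k_ciliary: 0.3
  variability:
    expression_sdlog: 0.35
    phi_sd: 0.08
quantify:
  threshold: otsu
  tilt_max: 60
  min_protrusion: 1
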