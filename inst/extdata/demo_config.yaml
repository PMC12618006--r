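# Demo configuration for the perfusion-FRET workflow: four K+ conditions
# with designed mean %ERK activities, a small population per condition.
seed: 7
k_levels: [5, 15, 30, 145]
target_percent: [5, 25, 55, 95]
n_dishes: 2
cells_per_dish: 10
noise_cv: 0.01
nonresponder_fraction: 0.1
k_sigma: 3
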