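parameter,our_method,system1,system2,ground_truth
area_mm2,5.99,6.04,5.76,5.89
mean_diameter_mm,2.72,2.72,2.66,2.68
min_diameter_mm,2.52,2.52,2.42,2.49
max_diameter_mm,2.91,2.93,2.87,2.88
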