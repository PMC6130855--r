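# reagent: O2+
# sample_id: group4-air-example
# group: 4
# condition: aerobic
# replicate: 1
# reagent_count_rate: 1e+06
# seed: NA
# scan_range: 10-200
mz,counts
83,1644
85,1342
87,152
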