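# Example routine-QA run configuration (units: cm, W)
scenario: 5H-flat-1.3
planes: [xy, xz]
spacing_cm: 1
power_W: 30
seed: 7
epd_convention: additional
axis_gate_pct: 80
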