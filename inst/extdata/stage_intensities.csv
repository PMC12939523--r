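"stage","climate_kg_co2e_per_cu"
"cultivation",0.15
"extraction",4.83
"sequestration",-1602.48
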