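"flow_name","category","factor","factor_unit"
"CO_2","climate_GWP100",1,"kg CO2-eq per kg"
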