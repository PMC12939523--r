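"ingredient","kg_co2e_per_kg"
"milk_chocolate",7
"sugar_from_sugarcane",0.6
"corn_glucose_syrup",1.2
"turmeric",2
"potato_starch",1
"spirulina_dried",15
"sugarcane_processing",0.5
"boiling_industrial",0.3
"beetroot_juice",1
"carrot_juice",1
"pet_granulate",2.5
"pp_granulate",1.8
"extrusion_plastic_film",0.45
"ldpe_granulate",2
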