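"ingredient","mass_kg","role"
"milk_chocolate",0.067,"raw"
"sugar_from_sugarcane",0.027,"raw"
"corn_glucose_syrup",0.004,"raw"
"turmeric",1e-04,"raw"
"potato_starch",0.0015,"raw"
"spirulina_dried",1e-04,"raw"
"sugarcane_processing",1e-04,"raw"
"boiling_industrial",1e-04,"raw"
"beetroot_juice",1e-04,"raw"
"carrot_juice",1e-04,"raw"
"dragee_production",NA,"production"
"pet_granulate",0.005,"packaging"
"pp_granulate",0.004,"packaging"
"extrusion_plastic_film",0.01,"packaging"
"ldpe_granulate",0.001,"packaging"
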