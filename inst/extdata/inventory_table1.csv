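"flow_name","amount","unit","compartment","direction_sign","stage","data_source","comment"
"Aluminum, cast alloy [GLO]",0.00434,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Battery, Li-ion [GLO]",0.00011,"kg","technosphere",1,"application","EcoInvent 3.9","For drone production"
"Cable [GLO]",1.83251e-05,"kg","technosphere",1,"application","EcoInvent 3.9","For drone production"
"CO_2",0.40179,"kg","elementary",-1,"cultivation","Elementary flow","For cultivation"
"CO_2",1.60248,"t","elementary",-1,"sequestration","Elementary flow","Carbon sequestration"
"Diesel [GLO]",8.13974,"MJ","technosphere",1,"application","EcoInvent 3.9","For drone operation"
"Electricity, high voltage [IS]",1.76167,"MJ","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Electricity, medium voltage [IS]",118.38543,"MJ","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Electronics, for control units [RER]",0.00641,"kg","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Glass-fiber-reinforced plastic, polyamide [RER]",0.00594,"kg","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Iron sulfate [GLO]",2.23214e-05,"kg","technosphere",1,"cultivation","EcoInvent 3.9","Nutrients"
"Land occupation",0.0032,"m2.a","elementary",1,"cultivation","Elementary flow","For cultivation"
"Light-Emitting Diode (LED) [GLO]",0.00538,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Nitrogen fertilizer, as N [GLO]",0.01116,"kg","technosphere",1,"cultivation","EcoInvent 3.9","Nutrients"
"Nylon 6-6 [RoW]",2.19901e-06,"kg","technosphere",1,"application","EcoInvent 3.9","For drone production"
"Polyethylene, high density [GLO]",0.00011,"kg","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Polypropylene [GLO]",0.00014,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Polyvinylchloride [GLO]",0.00141,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Silicone, at plant [GLO]",0.00012,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Sodium phosphate [RoW]",0.00893,"kg","technosphere",1,"cultivation","EcoInvent 3.9","Nutrients"
"Steel, chromium steel 18/8 [GLO]",0.00242,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Steel, unalloyed [RER]",0.00155,"kg","technosphere",1,"cultivation","EcoInvent 3.9","For bioreactor production"
"Tap water [IS]",37.29687,"kg","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Transport, freight, lorry 16-32 ton [GLO]",6.96354e-05,"t.km","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Transport, freight, lorry 3.5-7.5 ton [GLO]",1.75961,"t.km","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
"Transport, freight, transoceanic ship [GLO]",0.00443,"t.km","technosphere",1,"shared","EcoInvent 3.9","Used in multiple processes"
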