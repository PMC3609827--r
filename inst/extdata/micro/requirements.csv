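"nutrient_id","unit","min","max","sd"
"energy","kJ",11450,NA,184.4
"sat_fat","g",NA,30,0
"pufa","g",13.1,NA,0.655
"protein","g",52,NA,2.6
"fiber","g",30,NA,1.5
"sodium","mg",NA,2300,0
"potassium","mg",3800,NA,190
"calcium","mg",840,NA,42
"iron","mg",8,NA,0.4
"zinc","mg",12,NA,0.6
"selenium","ug",60,NA,3
"vit_a","ug RE",625,3000,31.25
"thiamine","mg",1,NA,0.05
"vit_c","mg",30,NA,1.5
"vit_e","mg",10,NA,0.5
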