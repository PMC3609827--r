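"id","name","category","price_mean","price_sd","wastage_mean","wastage_sd","ghg_factor","tags","nut_energy","nut_protein","nut_sat_fat","nut_pufa","nut_fiber","nut_sodium","nut_potassium","nut_calcium","nut_iron","nut_zinc","nut_selenium","nut_vit_a","nut_thiamine","nut_vit_c","nut_vit_e"
"flour_wholemeal","Wholemeal flour","cereal_grain",0.155960204126313,0.00779801020631567,0.05,0.002,0.804522440470755,"staple;requires_cooking_skill",2427.41439231672,12.2321541327983,0.402214760398492,1.04776442654198,10.4645420827204,3.10830320552923,699.38989581971,202.221554558515,3.42213597245514,4.33020924335533,19.5057888570159,0,0.434422585833818,0,1.12325705270671
"flour_white","White flour","cereal_grain",0.108028742730618,0.00540143713653088,0.04,0.002,0.785425959192216,"staple;requires_cooking_skill",2430.23350741315,9.84155802591704,0.29530316399876,0.875930642397143,2.86841064831242,2.97371287553105,289.410772186826,132.539100834121,1.15680970268324,1.11408709515068,16.1989396684179,0,0.290260883518495,0,0.399037073957808
"dried_peas","Dried peas","pulse_seed_nut",0.305166942975484,0.018310016578529,0.02,0.001,0.893323658555746,"pulse;requires_cooking_skill",2445.12897728468,22.9475602491992,0.205096465498209,0.596809756793082,23.6908843249083,12.4497340855189,1880.07300953861,365.566144321013,4.31188057501568,4.19065389816801,10.4519817923236,597.488368694293,0.701345700123347,2.9775304627768,0.439110058085779
"milk_powder","Skim milk powder","dairy",0.872526955204085,0.0523516173122451,0.01,0.001,9.41244224924594,"dairy_product;animal_product",2762.65477239871,36.0834615494125,0.510795781714842,0.0512032136647031,0,575.178610257572,3188.65409273995,8386.42141939199,0.311867180045228,6.04646069783588,23.9466703932072,603.887603512887,0.383320201216266,18.5880441935048,0
"vegetable_oil","Vegetable oil","fat_oil",0.456514061323833,0.0228257030661916,0,0,3.556781092647,"oil",6809.00715637159,0,8.1788594501093,62.147147661075,0,0,0,0,0,0,0,0,0,0,26.8766959393952
"potatoes","Potatoes","fruit_veg",0.273877606960014,0.0328653128352016,0.45,0.0142,0.404818780068308,"vegetable;starchy_root",591.697026209038,1.84342497545294,0.029146587545285,0.05210962611367,1.73775964365108,5.13085069414228,740.725988451586,39.4928725900336,0.393655736660585,0.602901594072976,0.790925419525633,77.5116313057068,0.0888553058404941,29.4224695372232,0.0144399700988826
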