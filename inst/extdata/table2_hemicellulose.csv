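"id","pretreatment","family","feedstock","target_fraction","target_location","temperature_C","pressure_bar","residence_time_min","log_severity","ri_cellulose","ri_hemicellulose","ri_lignin","accessibility_pct","citation"
"hemicellulose-steam_explosion","steam_explosion","thermal","Sugarcane bagasse","hemicellulose","liquor",195,,,3.67,2.3,81.7,12.1,92.8,"ref. 37"
"hemicellulose-LHW","LHW","thermal","Bermuda grass","hemicellulose","liquor",170,,,3.84,29.8,88.8,33.8,68.2,"ref. 48"
"hemicellulose-organosolv","organosolv","chemical","Wheat straw","hemicellulose","liquor",160,,,3.34,19.6,93.4,62.5,58.9,"ref. 41"
"hemicellulose-ionic_liquid","ionic_liquid","chemical","Switchgrass","hemicellulose","liquor",160,,,4.02,15.5,81.5,69.2,57.6,"ref. 42"
"hemicellulose-dilute_acid","dilute_acid","thermochemical","Bamboo green","hemicellulose","liquor",180,,,3.83,9.9,98.8,16.6,86.8,"ref. 43"
"hemicellulose-ARP","ARP","chemical","Corn stover","hemicellulose","liquor",170,23,,3.06,39.8,63.3,80.4,39.9,"ref. 49"
"hemicellulose-biological","biological","biological","Hardwood","hemicellulose","liquor",28,,,2.28,15.8,17.9,3,93.6,"ref. 47"
"hemicellulose-biological-1","biological","biological","Wheat straw","hemicellulose","liquor",28,,,2.48,16,94,49,67.5,"ref. 50"
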