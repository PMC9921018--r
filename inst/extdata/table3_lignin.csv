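"id","pretreatment","family","feedstock","target_fraction","target_location","temperature_C","pressure_bar","residence_time_min","log_severity","ri_cellulose","ri_hemicellulose","ri_lignin","accessibility_pct","citation"
"lignin-alkali","alkali","chemical","Eucalyptus camaldulensis","lignin","liquor",150,,,3.25,6.7,33.3,63.6,79.9,"ref. 51"
"lignin-kraft","kraft","chemical","Eucalyptus globulus","lignin","liquor",165,,,3.69,17.2,51,97.4,65.9,"ref. 40"
"lignin-LHW","LHW","thermal","Wheat straw","lignin","liquor",190,,,3.95,41.8,92.3,64.9,32.9,"ref. 52"
"lignin-ionic_liquid","ionic_liquid","chemical","Corn stover","lignin","liquor",140,,,3.43,49.4,56.9,94.4,46.8,"ref. 53"
"lignin-RAAE","RAAE","chemical","Corn stalks","lignin","liquor",85,20.4,,0.67,10.3,14.2,71.4,87.7,"ref. 32"
"lignin-organosolv","organosolv","chemical","Wheat straw","lignin","liquor",160,,,3.37,19.6,93.4,62.5,43.5,"ref. 41"
"lignin-ARP","ARP","chemical","Corn stover","lignin","liquor",170,23,,3.06,39.8,63.3,80.4,79.9,"ref. 49"
"lignin-biological","biological","biological","Bamboo culms","lignin","liquor",60,,,2.28,8.8,53.3,95.6,,"ref. 54"
"lignin-biological-1","biological","biological","Corn stover","lignin","liquor",28,,,2.66,58,51,64,45.5,"ref. 55"
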