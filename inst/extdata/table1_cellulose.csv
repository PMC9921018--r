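"id","pretreatment","family","feedstock","target_fraction","target_location","temperature_C","pressure_bar","residence_time_min","log_severity","ri_cellulose","ri_hemicellulose","ri_lignin","accessibility_pct","citation"
"cellulose-kraft","kraft","chemical","Eucalyptus globulus","cellulose","WIS",155,,,3.09,10,39.4,84.6,62,"ref. 40"
"cellulose-organosolv","organosolv","chemical","Wheat straw","cellulose","WIS",160,,,3.37,19.6,93.4,62.5,77.9,"ref. 41"
"cellulose-ionic_liquid","ionic_liquid","chemical","Corn stover","cellulose","WIS",160,,,4.02,15.5,81.5,69.2,75.4,"ref. 42"
"cellulose-dilute_acid","dilute_acid","thermochemical","Bamboo green","cellulose","WIS",180,,,3.83,9.9,98.8,16.6,57.7,"ref. 43"
"cellulose-RAAE","RAAE","chemical","Corn stalks","cellulose","WIS",85,20.4,,0.67,10.3,14.1,71.4,42.8,"ref. 32"
"cellulose-wet_air_oxidation","wet_air_oxidation","thermochemical","Rice husk","cellulose","WIS",195,5,,3.79,7.1,75.5,97.3,86.4,"ref. 44"
"cellulose-AFEX","AFEX","chemical","Corn stover","cellulose","WIS",130,44.8,,2.06,27.8,34.6,23.5,29.1,"ref. 45"
"cellulose-biological","biological","biological","Corn stalks","cellulose","WIS",28,,,2.66,57,41,11,14.1,"ref. 46"
"cellulose-biological-1","biological","biological","Switchgrass","cellulose","WIS",28,,,2.29,22,14,24,81,"ref. 47"
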