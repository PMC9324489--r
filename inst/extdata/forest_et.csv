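dbh_cm,density_per_hm2,et_per_plant_kg,et_m3_per_km2
15,800,1667.6,133408
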