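{"label":"phantom4","hb_mg_per_ml":0.5,"polystyrene_pct":0.5,"nadh_ug_per_ml":1,"carbostyril_ug_per_ml":1,"bead_diameter_um":1,"thickness_cm":1,"temperature_c":22}
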