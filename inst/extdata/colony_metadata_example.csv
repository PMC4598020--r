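colony_id,chamber_id,species,site,surface_area_m2
col01,F1,S. cf. stellata,salvador,0.0011
col02,F2,S. cf. stellata,salvador,0.0014
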