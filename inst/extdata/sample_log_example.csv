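# units: ta=umol_kg o2=umol_L salinity=psu temperature=degC volume=L
chamber_id,role,phase,cycle,time,ta,o2,salinity,temperature,extracted_l,residual_l
F1,treatment,light,C1,11:00:00,2302.1,204.8,35.3,28.6,,
F1,treatment,light,C1,14:00:00,2266.4,218.7,35.3,28.7,0.100,0.975
F2,treatment,light,C1,11:00:00,2299.8,205.3,35.3,28.6,,
F2,treatment,light,C1,14:00:00,2259.1,224.6,35.3,28.7,0.100,0.950
B1,control,light,C1,11:00:00,2301.0,205.1,35.3,28.6,,
B1,control,light,C1,14:00:00,2300.2,205.6,35.3,28.7,0.100,1.000
F1,treatment,dark,C2,15:30:00,2301.5,204.9,35.3,28.7,,
F1,treatment,dark,C2,18:30:00,2271.9,195.0,35.3,28.6,0.100,0.975
F2,treatment,dark,C2,15:30:00,2300.6,205.0,35.3,28.7,,
F2,treatment,dark,C2,18:30:00,2267.0,191.1,35.3,28.6,0.100,0.950
B1,control,dark,C2,15:30:00,2300.8,205.2,35.3,28.7,,
B1,control,dark,C2,18:30:00,2300.1,204.9,35.3,28.6,0.100,1.000
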