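volume_ml,hour,phase,o2_state,met_change
250,1,light,+,+
250,2,light,+,+
250,3,light,+,+
250,4,light,+,+
500,1,light,+/-,+
500,2,light,+,+
500,3,light,+,+
500,4,light,+,+
750,1,light,+/-,+
750,2,light,+/-,+
750,3,light,+,+
750,4,light,+,+
1000,1,light,-,+/-
1000,2,light,-,+
1000,3,light,-,+
1000,4,light,+/-,+
1250,1,light,-,+
1250,2,light,-,+/-
1250,3,light,-,+
1250,4,light,-,+
1500,1,light,-,-
1500,2,light,-,+/-
1500,3,light,-,+/-
1500,4,light,-,+
250,1,dark,+,+
250,2,dark,+,+
250,3,dark,+,+
250,4,dark,+,+
500,1,dark,+,+/-
500,2,dark,+,+
500,3,dark,+,+
500,4,dark,+,+
750,1,dark,-,+
750,2,dark,-,+
750,3,dark,+/-,+
750,4,dark,+,+
1000,1,dark,-,+/-
1000,2,dark,-,+
1000,3,dark,-,+
1000,4,dark,+/-,+
1250,1,dark,-,-
1250,2,dark,-,+/-
1250,3,dark,-,+
1250,4,dark,-,+
1500,1,dark,-,-
1500,2,dark,-,-
1500,3,dark,-,-
1500,4,dark,-,+/-
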