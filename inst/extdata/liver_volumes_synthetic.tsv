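patient_id	tlv	remnant	followup
P01	1510	560	1180
P02	1320	420	980
P03	1740	690	1350
P04	1190	380	640
P05	1460	510	1230
P06	1610	480	870
P07	1280	450	1040
P08	1390	530	1160
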