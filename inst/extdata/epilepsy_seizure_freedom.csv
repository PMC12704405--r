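study_id,n_treat,n_ctrl,events_treat,events_ctrl
Ben-Menachem 1996,28,28,,
Elterman 1999,41,45,4,2
Faught 1996,136,45,,
Guberman 2002,171,92,10,2
Korean 1999,91,86,7,1
Privitera 1996,143,47,,
Rosenfeld 1996,167,42,,
Sharief 1996,23,24,2,0
Tassinari 1996,30,30,0,0
Yen 2000,23,23,,
Zhang 2011,46,40,0,0
Coles 1999,52,51,,
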