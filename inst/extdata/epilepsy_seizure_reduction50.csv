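study_id,n_treat,n_ctrl,events_treat,events_ctrl
Ben-Menachem 1996,28,28,12,0
Elterman 1999,41,45,16,9
Faught 1996,136,45,54,8
Guberman 2002,171,92,77,22
Korean 1999,91,86,45,11
Privitera 1996,143,47,58,4
Rosenfeld 1996,167,42,86,8
Sharief 1996,23,24,8,2
Tassinari 1996,30,30,14,3
Yen 2000,23,23,11,3
Zhang 2011,46,40,22,3
Coles 1999,52,51,,
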