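"sample_id","group","m0","m1","m2","m3","m4","m5","rinf_acac_nominal","rinf_bhb_nominal"
"fed_01","fed",0.387917,0.225384,0.073122,0.102506,0.189626,0.021446,1.91,2.08
"fed_02","fed",0.393222,0.238106,0.071565,0.087199,0.194718,0.01519,1.91,2.08
"fed_03","fed",0.390948,0.232101,0.072319,0.095642,0.186939,0.022051,1.91,2.08
"fasted_01","fasted",0.547816,0.25042,0.058207,0.037141,0.094863,0.011552,1.91,2.08
"fasted_02","fasted",0.550192,0.248694,0.06392,0.034917,0.092514,0.009764,1.91,2.08
"fasted_03","fasted",0.543968,0.251583,0.062821,0.032511,0.09949,0.009628,1.91,2.08
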