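pair_id,printed_p_galler,printed_p_nongaller
Euurina,0.059,0.94
Bacconematus,1.00,0.50
Pristolina,0.50,0.67
Micronematus,0.97,0.033
Kladothrips,0.21,0.83
Cynipidae,0.24,0.76
Agaonidae,0.15,0.85
Eurostina,0.54,0.48
Oedapidina,0.71,0.30
Hexomyza,0.95,0.054
Apiomorpha,0.020,0.99
Maskellia,1.00,0.0023
Cerataphidini,0.053,0.96
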