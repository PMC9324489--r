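city,country,use_million_m3
Kronoberg,Sweden,17.42
Esbjerg,Denmark,14.30
Aust-Agder,Norway,15.67
Tartu,Estonia,6.75
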