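name,M,hc,fr,eta
sleep,40,2.7,0.35,0
light_work,75,4.0,0.70,0
moderate_work,220,8.2,0.73,0
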