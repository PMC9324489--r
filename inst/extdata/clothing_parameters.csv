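season,fcl,icl_thermal,icl_perm
spring,1.22,0.89,0.50
summer,1.10,0.36,0.55
autumn,1.28,1.01,0.48
winter,1.33,1.20,0.43
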