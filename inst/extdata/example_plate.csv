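drug,cell_line,concentration,concentration_unit,replicate,viability_pct
PLX-4720,YUMM1.7,0,uM,1,96.8677309462883
PLX-4720,YUMM1.7,0,uM,2,100.91821662111
PLX-4720,YUMM1.7,0.375,uM,1,78.0409181043793
PLX-4720,YUMM1.7,0.375,uM,2,90.1954651771185
PLX-4720,YUMM1.7,0.75,uM,1,71.454302144101
PLX-4720,YUMM1.7,0.75,uM,2,65.7044213644341
PLX-4720,YUMM1.7,1.5,uM,1,56.0549560228103
PLX-4720,YUMM1.7,1.5,uM,2,57.309434286314
PLX-4720,YUMM1.7,3,uM,1,39.5075506112459
PLX-4720,YUMM1.7,3,uM,2,35.1017019171967
PLX-4720,YUMM1.7,6,uM,1,29.9793868352721
PLX-4720,YUMM1.7,6,uM,2,24.369697175075
PLX-4720,YUMM1.7,12,uM,1,9.51939779628618
PLX-4720,YUMM1.7,12,uM,2,1.5521012631077
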