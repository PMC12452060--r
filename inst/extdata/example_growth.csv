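mouse_id,cell_line,host,day,volume_mm3
m01,B16F0,NSG,4,2.60506075773847
m01,B16F0,NSG,6,13.7644944487631
m01,B16F0,NSG,8,41.7720082482122
m01,B16F0,NSG,10,128.989374491361
m01,B16F0,NSG,12,575.888835511872
m02,B16F0,NSG,4,4.41682149366997
m02,B16F0,NSG,6,18.7168519040293
m02,B16F0,NSG,8,67.4260901378325
m02,B16F0,NSG,10,239.112476923005
m02,B16F0,NSG,12,921.216854042296
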