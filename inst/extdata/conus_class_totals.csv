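class,n_wetlands,total_area_km2
Riparian,2679963,294410
NRShw,621659,35767
NRMid,1646321,43399
NRDeep,1702633,38992
Unclassified,12417,644
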