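variable,flag
mortality,-1
winter mortality,-1
shoot mortality,-1
dig time,-1
time to dig,-1
abundance,1
flower abundance,1
shoot growth,1
psii activity,1
photosynthetic rate,1
body mass,1
reproductive success,1
calf at heel,1
population growth rate,1
survival,1
chlorophyll fluorescence,1
nitrogen fixation,1
berry production,1
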