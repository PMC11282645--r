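"name","location","site_z","tracer_concentration_uM","bolus_volume_ml","bolus_rate_ml_min","flush_volume_ml","flush_rate_ml_min"
"2NHP2","L4/L5",-272,331,0.5,1,1.5,1
"3G1","L3/L4",-264,331,0.5,1,1.5,1
"1NHP1","L3/L4",-264,165.5,1,1,0,0
"3G2","L3/L4",-264,82.75,2,1,0,0
"1NHP3","L4/L5",-272,165.5,1,0.1,0,0
"1NHP2","L4/L5",-272,165.5,1,1,0,0
"2G2","L4/L5",-272,165.5,1,1,1.5,1
"5NHP1","L4/L5",-272,165.5,1,1,1.5,0.5
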