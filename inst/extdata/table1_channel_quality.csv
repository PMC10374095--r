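animal,condition,channel,pct_dropped,pct_artifact,power
58-21,baseline,1,0.5,2.0,7.6e+07
58-21,baseline,2,0.5,6.1,8.3e+08
58-21,baseline,3,0.5,1.9,1.4e+08
58-21,baseline,4,0.5,1.2,1.2e+08
58-21,feeding,1,18.3,6.5,2.0e+08
58-21,feeding,2,18.4,2.8,3.1e+08
58-21,feeding,3,17.9,7.3,4.0e+08
58-21,feeding,4,18.2,5.4,2.3e+08
60-21,baseline,1,0.5,3.0,3.0e+08
60-21,baseline,2,0.5,0.6,7.2e+07
60-21,baseline,3,1.3,51.2,8.7e+08
60-21,baseline,4,0.5,7.9,6.7e+08
60-21,feeding,1,4.4,9.6,4.6e+08
60-21,feeding,2,0.9,4.8,1.4e+08
60-21,feeding,3,1.6,57.2,8.7e+08
60-21,feeding,4,0.9,8.6,4.1e+08
87-21,baseline,1,2.8,2.2,1.9e+08
87-21,baseline,2,0.7,4.6,9.1e+07
87-21,baseline,3,0.2,3.1,7.7e+07
87-21,baseline,4,0.1,0.4,2.0e+07
87-21,feeding,1,2.6,2.4,1.2e+08
87-21,feeding,2,6.4,12.7,4.7e+08
87-21,feeding,3,3.9,40.9,9.8e+08
87-21,feeding,4,0.3,0.9,9.5e+07
103-21,baseline,1,0.0,1.4,2.0e+08
103-21,baseline,2,0.0,0.0,1.5e+08
103-21,baseline,3,0.0,0.0,6.4e+07
103-21,baseline,4,0.0,0.0,4.9e+07
103-21,feeding,1,0.0,4.5,5.7e+08
103-21,feeding,2,0.0,0.0,2.0e+08
103-21,feeding,3,0.0,0.1,1.4e+08
103-21,feeding,4,0.0,0.0,7.4e+07
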