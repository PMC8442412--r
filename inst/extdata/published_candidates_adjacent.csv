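gender,stratum,B,level,accuracy,sensitivity
men,U58-U63,19.5,19,0.609,NA
men,U58-U63,19.5,20,0.615,NA
men,U58-U63,19.5,21,0.622,NA
men,U63-U68,20.1,19,0.479,NA
men,U63-U68,20.1,20,0.480,NA
men,U63-U68,20.1,21,0.492,NA
men,U68-U80,20.5,20,0.522,NA
men,U68-U80,20.5,21,0.516,NA
men,U68-U80,20.5,22,0.526,NA
men,U80-O80,20.0,19,0.459,NA
men,U80-O80,20.0,20,0.473,NA
men,U80-O80,20.0,21,0.502,NA
women,U49-U53,16.0,15,0.468,NA
women,U49-U53,16.0,16,0.436,NA
women,U49-U53,16.0,17,0.412,NA
women,U53-U57,17.5,17,0.605,NA
women,U53-U57,17.5,18,0.608,NA
women,U53-U57,17.5,19,0.610,NA
women,U57-U67,18.2,17,0.448,NA
women,U57-U67,18.2,18,0.434,NA
women,U57-U67,18.2,19,0.426,NA
women,U67-O67,17.3,16,0.530,NA
women,U67-O67,17.3,17,0.541,NA
women,U67-O67,17.3,18,0.572,NA
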