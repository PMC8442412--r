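gender,stratum,A,B,level,accuracy,sensitivity
men,U58,18,18.8,18,0.365,NA
men,U58,18,18.8,19,0.329,NA
men,U58,18,18.8,20,0.309,NA
men,U63,20,20.4,19,0.482,NA
men,U63,20,20.4,20,0.464,NA
men,U63,20,20.4,21,0.426,NA
men,U68,21,19.3,18,0.486,NA
men,U68,21,19.3,19,0.494,NA
men,U68,21,19.3,20,0.478,NA
men,U80,23,19.5,19,0.445,NA
men,U80,23,19.5,20,0.423,NA
men,U80,23,19.5,21,0.401,NA
men,O80,25,19.0,18,0.458,NA
men,O80,25,19.0,19,0.496,0.674
men,O80,25,19.0,20,0.496,0.689
women,U49,16,16.0,15,0.489,NA
women,U49,16,16.0,16,0.466,NA
women,U49,16,16.0,17,0.454,NA
women,U53,17,16.0,15,0.525,NA
women,U53,17,16.0,16,0.499,NA
women,U53,17,16.0,17,0.485,NA
women,U57,18,18.0,17,0.498,NA
women,U57,18,18.0,18,0.486,NA
women,U57,18,18.0,19,0.475,NA
women,U67,20,17.3,16,0.443,NA
women,U67,20,17.3,17,0.433,NA
women,U67,20,17.3,18,0.382,NA
women,O67,22,16.8,17,0.462,NA
women,O67,22,16.8,18,0.473,NA
women,O67,22,16.8,19,0.467,NA
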