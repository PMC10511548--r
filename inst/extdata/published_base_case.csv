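country,cancer,agent,strategy,cost,fn_avoided,ly,qaly,icer_fn,icer_ly,icer_qaly
Austria,BC,filgrastim,PP,1567,0.135,13.024,10.997,5840,8029,9219
Austria,BC,filgrastim,SP,980,0.035,12.951,10.934,Reference,Reference,Reference
Austria,NSCLC,filgrastim,PP,1847,0.156,8.743,6.023,972,758,1069
Austria,NSCLC,filgrastim,SP,1736,0.041,8.597,5.919,Reference,Reference,Reference
Austria,NHL,filgrastim,PP,2506,0.172,8.348,7.266,5459,4195,4646
Austria,NHL,filgrastim,SP,1862,0.054,8.194,7.127,Reference,Reference,Reference
Austria,BC,pegfilgrastim,PP,1787,0.168,13.099,11.063,6724,9205,10568
Austria,BC,pegfilgrastim,SP,959,0.045,13.009,10.984,Reference,Reference,Reference
Austria,NSCLC,pegfilgrastim,PP,1957,0.194,8.791,6.057,2036,1558,2199
Austria,NSCLC,pegfilgrastim,SP,1672,0.054,8.608,5.927,Reference,Reference,Reference
Austria,NHL,pegfilgrastim,PP,2751,0.212,8.397,7.310,6781,4926,5458
Austria,NHL,pegfilgrastim,SP,1786,0.070,8.201,7.133,Reference,Reference,Reference
France,BC,filgrastim,PP,1880,0.135,12.943,10.928,4489,6211,7131
France,BC,filgrastim,SP,1430,0.035,12.870,10.865,Reference,Reference,Reference
France,NSCLC,filgrastim,PP,2323,0.156,8.272,5.697,Dominates,Dominates,Dominates
France,NSCLC,filgrastim,SP,2475,0.041,8.134,5.599,Reference,Reference,Reference
France,NHL,filgrastim,PP,3165,0.172,7.974,6.933,6421,5248,5807
France,NHL,filgrastim,SP,2407,0.054,7.829,6.802,Reference,Reference,Reference
France,BC,pegfilgrastim,PP,2406,0.168,13.014,10.990,8039,11076,12715
France,BC,pegfilgrastim,SP,1416,0.045,12.925,10.912,Reference,Reference,Reference
France,NSCLC,pegfilgrastim,PP,2656,0.194,8.316,5.729,1839,1499,2112
France,NSCLC,pegfilgrastim,SP,2398,0.054,8.144,5.607,Reference,Reference,Reference
France,NHL,pegfilgrastim,PP,3656,0.212,8.020,6.974,9358,7233,8008
France,NHL,pegfilgrastim,SP,2325,0.070,7.836,6.808,Reference,Reference,Reference
Germany,BC,filgrastim,PP,2411,0.135,13.812,11.675,18781,24334,27960
Germany,BC,filgrastim,SP,525,0.035,13.734,11.608,Reference,Reference,Reference
Germany,NSCLC,filgrastim,PP,2554,0.156,8.650,5.959,13550,10698,15090
Germany,NSCLC,filgrastim,SP,1003,0.041,8.505,5.856,Reference,Reference,Reference
Germany,NHL,filgrastim,PP,3904,0.172,8.397,7.310,20909,15878,17588
Germany,NHL,filgrastim,SP,1437,0.054,8.242,7.169,Reference,Reference,Reference
Germany,BC,pegfilgrastim,PP,4077,0.168,13.889,11.742,27862,35951,41305
Germany,BC,pegfilgrastim,SP,646,0.045,13.794,11.659,Reference,Reference,Reference
Germany,NSCLC,pegfilgrastim,PP,4181,0.194,8.697,5.992,21932,17003,23990
Germany,NSCLC,pegfilgrastim,SP,1108,0.054,8.517,5.864,Reference,Reference,Reference
Germany,NHL,pegfilgrastim,PP,6252,0.212,8.447,7.354,32746,23499,26046
Germany,NHL,pegfilgrastim,SP,1594,0.070,8.248,7.175,Reference,Reference,Reference
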