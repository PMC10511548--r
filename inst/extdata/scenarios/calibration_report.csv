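id,country,cancer,agent,gcsf_cost_per_cycle,drug_unit_price,fn_hospitalisation_cost,pp_cost_residual,sp_cost_residual,provenance
austria_bc_filgrastim,Austria,BC,filgrastim,200.122531466317,20.0122531466317,4570.80631533607,4.54747350886464e-13,0,calibrated
austria_bc_pegfilgrastim,Austria,BC,pegfilgrastim,264.796488618632,264.796488618632,4616.21905085263,0,0,calibrated
austria_nsclc_filgrastim,Austria,NSCLC,filgrastim,192.40037264886,19.240037264886,7362.77261626744,2.27373675443232e-13,-2.27373675443232e-13,calibrated
austria_nsclc_pegfilgrastim,Austria,NSCLC,pegfilgrastim,262.589999991578,262.589999991578,7462.52993049962,2.27373675443232e-13,0,calibrated
austria_nhl_filgrastim,Austria,NHL,filgrastim,298.952029112778,29.8952029112778,7513.82631861491,4.54747350886464e-13,0,calibrated
austria_nhl_pegfilgrastim,Austria,NHL,pegfilgrastim,394.753122581276,394.753122581276,7525.26162751812,0,4.54747350886464e-13,calibrated
france_bc_filgrastim,France,BC,filgrastim,219.883946923342,21.9883946923342,6842.31793656453,0,-4.54747350886464e-13,calibrated
france_bc_pegfilgrastim,France,BC,pegfilgrastim,349.465732389096,349.465732389096,6912.80183210402,4.54747350886464e-13,4.54747350886464e-13,calibrated
france_nsclc_filgrastim,France,NSCLC,filgrastim,218.696837529335,21.8696837529335,10601.4558241547,0,0,calibrated
france_nsclc_pegfilgrastim,France,NSCLC,pegfilgrastim,349.089392743249,349.089392743249,10741.7375454044,0,0,calibrated
france_nhl_filgrastim,France,NHL,filgrastim,371.781946484727,37.1781946484727,9716.28715725763,-4.54747350886464e-13,0,calibrated
france_nhl_pegfilgrastim,France,NHL,pegfilgrastim,524.642622170552,524.642622170552,9728.04660616065,-4.54747350886464e-13,4.54747350886464e-13,calibrated
germany_bc_filgrastim,Germany,BC,filgrastim,381.270667556953,38.1270667556953,1690.77579873151,4.54747350886464e-13,0,calibrated
germany_bc_pegfilgrastim,Germany,BC,pegfilgrastim,671.165145060818,671.165145060818,1641.3501443877,0,0,calibrated
germany_nsclc_filgrastim,Germany,NSCLC,filgrastim,372.065446213095,37.2065446213095,3581.70944849299,-4.54747350886464e-13,0,calibrated
germany_nsclc_pegfilgrastim,Germany,NSCLC,pegfilgrastim,670.552759001694,670.552759001694,3562.36209164538,0,0,calibrated
germany_nhl_filgrastim,Germany,NHL,filgrastim,576.135811814997,57.6135811814997,4859.53542860322,-4.54747350886464e-13,0,calibrated
germany_nhl_pegfilgrastim,Germany,NHL,pegfilgrastim,1005.58954213045,1005.58954213045,4792.42478705412,0,-2.27373675443232e-13,calibrated
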