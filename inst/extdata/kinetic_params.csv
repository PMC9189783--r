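strain,series,model,x0,x0_se,xmax,xmax_se,mu_max,mu_max_se,g,g_se,pmax,pmax_se,rmax,rmax_se,tlag,tlag_se,yps,yxs,ypx,qp,qs,adj_r2,rmse,mae
mutant,biomass,logistic,3.29,0.28,482.46,27.36,0.578,0.01,0.36,0.01,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.9909,17.00,13.90
wild,biomass,logistic,0.61,0.03,228.65,18.46,0.362,0.01,0.522,0.01,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,0.9867,10.66,7.79
mutant,protein,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,7644.62,108.32,315.46,32.43,5.07,0.64,NA,NA,NA,NA,NA,0.9989,81.04,56.89
wild,protein,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,132.05,5.32,27.55,2.84,7.15,0.86,NA,NA,NA,NA,NA,0.9703,8.84,7.11
mutant,activity,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,820953.05,26388.52,44529.23,3527.11,5.41,0.32,NA,NA,NA,NA,NA,0.9996,24.90,242.49
wild,activity,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,76.73,11.83,28.16,9.82,7.36,1.04,NA,NA,NA,NA,NA,0.984,7.25,6.78
mutant,substrate,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,7250.25,122.67,397.64,30.23,3.38,0.37,1.054,0.067,0.016,0.511,0.461,0.9997,43.17,34.16
wild,substrate,gompertz,NA,NA,NA,NA,NA,NA,NA,NA,2919.22,32.17,202.20,12.53,2.51,0.25,0.045,0.078,0.00058,0.02,0.381,0.9770,150.45,109.31
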