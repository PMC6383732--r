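study,species,experiment_id,treatment,pco2_uatm,ph_nbs,duration_days,daily_mortality,larval_size_mm
synthstudy1,synthsp2,exp1,ambient,450,8.1,20,0.07606,4
synthstudy1,synthsp2,exp1,acidified,750,7.9,20,0.09234,4
synthstudy1,synthsp2,exp1,acidified,1200,7.6,20,0.10464,4
synthstudy1,synthsp2,exp1,acidified,1650,7.3,20,0.11339,4
synthstudy2,synthsp3,exp2,ambient,450,8.1,20,0.03778,5
synthstudy2,synthsp3,exp2,acidified,750,7.9,20,0.0448,5
synthstudy2,synthsp3,exp2,acidified,1200,7.6,20,0.06101,5
synthstudy2,synthsp3,exp2,acidified,1650,7.3,20,0.0728,5
synthstudy3,synthsp4,exp3,ambient,450,8.1,20,0.02797,6
synthstudy3,synthsp4,exp3,acidified,750,7.9,20,0.03598,6
synthstudy3,synthsp4,exp3,acidified,1200,7.6,20,0.05274,6
synthstudy3,synthsp4,exp3,acidified,1650,7.3,20,0.06501,6
synthstudy4,synthsp1,exp4,ambient,450,8.1,20,0.09537,3
synthstudy4,synthsp1,exp4,acidified,750,7.9,20,0.11045,3
synthstudy4,synthsp1,exp4,acidified,1200,7.6,20,0.12316,3
synthstudy4,synthsp1,exp4,acidified,1650,7.3,20,0.13396,3
synthstudy5,synthsp2,exp5,ambient,450,8.1,20,0.09096,4
synthstudy5,synthsp2,exp5,acidified,750,7.9,20,0.10211,4
synthstudy5,synthsp2,exp5,acidified,1200,7.6,20,0.11151,4
synthstudy5,synthsp2,exp5,acidified,1650,7.3,20,0.12805,4
synthstudy6,synthsp3,exp6,ambient,450,8.1,20,0.111,5
synthstudy6,synthsp3,exp6,acidified,750,7.9,20,0.12114,5
synthstudy6,synthsp3,exp6,acidified,1200,7.6,20,0.13529,5
synthstudy6,synthsp3,exp6,acidified,1650,7.3,20,0.14906,5
synthstudy7,synthsp4,exp7,ambient,450,8.1,20,0.05137,6
synthstudy7,synthsp4,exp7,acidified,750,7.9,20,0.05851,6
synthstudy7,synthsp4,exp7,acidified,1200,7.6,20,0.07119,6
synthstudy7,synthsp4,exp7,acidified,1650,7.3,20,0.08414,6
synthstudy8,synthsp1,exp8,ambient,450,8.1,20,0.09313,3
synthstudy8,synthsp1,exp8,acidified,750,7.9,20,0.10268,3
synthstudy8,synthsp1,exp8,acidified,1200,7.6,20,0.11133,3
synthstudy8,synthsp1,exp8,acidified,1650,7.3,20,0.12669,3
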