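set,patient_id,primary_site,tnm,hpv,recur,rfs_days,rt_auc,growth_rate,z_auc_printed,z_growth_printed,oncosensi_printed
test,1,Base of Tongue,cT3N0M0,negative,no,481,535.7,258.5,0.1556,0.5761,0.712
test,2,Base of Tongue,cT3N2M0,positive,no,512,337.7,200,-1.2579,0.2025,-1.738
test,3,Tonsil,cT3N2M0,positive,no,539,691.1,73.8,1.2651,-1.2493,0.678
test,4,Oropharynx,cT2N2bM0,negative,no,841,543.8,129,0.2135,-0.4361,-0.502
test,5,Oropharynx,cT2N1M0,negative,yes,131,657.3,140,1.0238,-0.3169,0.625
test,6,Tonsil,cT2N1M0,positive,no,463,465.8,82.8,-0.3434,-1.0818,-1.702
test,7,Tonsil,cT2N1M0,positive,no,795,374.9,262,-0.9924,0.5957,-0.777
test,8,Tonsil,cT1N1M0,positive,no,816,565.4,73.6,0.3677,-1.2533,-0.852
test,9,tonsil,cT2N2M0,positive,no,784,665,83.5,1.0788,-1.0695,0.187
test,10,tonsil,cT2N1M0,positive,no,631,295.9,417.9,-1.5564,1.2756,0.036
test,11,tonsil,cT2N2M0,positive,no,446,449.7,424.3,-0.4583,1.2977,1.553
test,12,tonsil,cT2N1M0,positive,yes,273,384.5,365.4,-0.9238,1.0801,0.659
test,13,tonsil,cT2N2M0,negative,yes,229,746.5,100,1.6606,-0.8069,1.122
test,14,Oropharynx,cT2N1M0,negative,yes,316,481.3,393,-0.2327,1.1861,1.539
validation,1,glottis,PT4aN1M0,NA,yes,NA,719.4,152.6,1.467,-0.188,1.731
validation,2,glottis,pT2N0M0,NA,yes,NA,800,139.2,2.043,-0.321,2.335
validation,3,glottis,pT4aN1M0,NA,yes,NA,800,143.1,2.043,-0.281,2.386
validation,4,glottis,pT4N0M0,NA,yes,NA,800,131.7,2.043,-0.401,2.234
validation,5,glottis,pT4aN0M0,NA,yes,NA,634.5,260.4,0.861,0.585,1.895
validation,6,glottis,pT4aN0M0,NA,yes,NA,513.1,500,-0.006,1.530,1.926
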