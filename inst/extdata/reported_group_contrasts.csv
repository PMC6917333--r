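feature_id,adjusted_diff,f_stat,df1,df2,eta2_reported
L thalamus proper volume/GM,-0.00201,13.084,1,23,0.363
L thalamus proper volume/ICV,-0.00099,22.923,1,23,0.499
L putamen volume/ICV,-0.00054,7.589,1,23,0.248
L hippocampus volume/GM,-0.00084,5.190,1,23,0.184
L hippocampus volume/ICV,-0.00047,12.168,1,23,0.346
R thalamus proper volume/ICV,-0.00060,8.258,1,23,0.264
R caudate volume/ICV,-0.00038,6.519,1,23,0.221
R putamen volume/GM,-0.00109,14.384,1,23,0.385
R putamen volume/ICV,-0.00060,19.781,1,23,0.462
R pallidum volume/ICV,-0.00015,7.841,1,23,0.254
R hippocampus volume/ICV,-0.00039,8.342,1,23,0.266
ICV,184623.56089,11.589,1,23,0.335
L fusiform volume,-802.67619,7.342,1,23,0.242
L pars opercularis thickness,0.10483,5.801,1,23,0.201
L lingual thickness,0.12534,6.347,1,23,0.216
L pars opercularis roughness,0.06729,4.839,1,23,0.174
L superior parietal roughness,0.10372,8.456,1,23,0.269
L inferior parietal roughness,0.11265,8.287,1,23,0.265
L precuneus roughness,0.09910,9.248,1,23,0.287
R superior parietal volume,5867.17619,62.627,1,23,0.731
R superior parietal thickness,0.46694,41.654,1,23,0.644
R middle temporal thickness,0.20840,4.506,1,23,0.164
R isthmus cingulate thickness,0.17141,5.698,1,23,0.199
R superior parietal roughness,0.09128,9.634,1,23,0.295
R inferior parietal roughness,0.10284,26.297,1,23,0.533
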