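subject_id,group,rater_id,feature_id,lobe,score
S1,CF,A,viscosity,RUL,0
S1,CF,A,viscosity,RML,0
S1,CF,A,viscosity,RLL,0
S1,CF,A,viscosity,LUL,0
S1,CF,A,viscosity,LLL,0
S1,CF,B,viscosity,RUL,1
S1,CF,B,viscosity,RML,0
S1,CF,B,viscosity,RLL,0
S1,CF,B,viscosity,LUL,0
S1,CF,B,viscosity,LLL,0
S2,CF,A,viscosity,RUL,1
S2,CF,A,viscosity,RML,1
S2,CF,A,viscosity,RLL,1
S2,CF,A,viscosity,LUL,0
S2,CF,A,viscosity,LLL,0
S2,CF,B,viscosity,RUL,2
S2,CF,B,viscosity,RML,1
S2,CF,B,viscosity,RLL,1
S2,CF,B,viscosity,LUL,1
S2,CF,B,viscosity,LLL,0
S3,nonCF,A,viscosity,RUL,2
S3,nonCF,A,viscosity,RML,2
S3,nonCF,A,viscosity,RLL,2
S3,nonCF,A,viscosity,LUL,0
S3,nonCF,A,viscosity,LLL,0
S3,nonCF,B,viscosity,RUL,2
S3,nonCF,B,viscosity,RML,2
S3,nonCF,B,viscosity,RLL,2
S3,nonCF,B,viscosity,LUL,2
S3,nonCF,B,viscosity,LLL,2
S1,CF,A,secretion_color,RUL,0
S1,CF,A,secretion_color,RML,0
S1,CF,A,secretion_color,RLL,0
S1,CF,A,secretion_color,LUL,0
S1,CF,A,secretion_color,LLL,0
S1,CF,B,secretion_color,RUL,2
S1,CF,B,secretion_color,RML,0
S1,CF,B,secretion_color,RLL,0
S1,CF,B,secretion_color,LUL,0
S1,CF,B,secretion_color,LLL,0
S2,CF,A,secretion_color,RUL,3
S2,CF,A,secretion_color,RML,0
S2,CF,A,secretion_color,RLL,5
S2,CF,A,secretion_color,LUL,2
S2,CF,A,secretion_color,LLL,0
S2,CF,B,secretion_color,RUL,4
S2,CF,B,secretion_color,RML,0
S2,CF,B,secretion_color,RLL,5
S2,CF,B,secretion_color,LUL,1
S2,CF,B,secretion_color,LLL,0
S3,nonCF,A,secretion_color,RUL,8
S3,nonCF,A,secretion_color,RML,8
S3,nonCF,A,secretion_color,RLL,8
S3,nonCF,A,secretion_color,LUL,8
S3,nonCF,A,secretion_color,LLL,8
S3,nonCF,B,secretion_color,RUL,7
S3,nonCF,B,secretion_color,RML,8
S3,nonCF,B,secretion_color,RLL,6
S3,nonCF,B,secretion_color,LUL,8
S3,nonCF,B,secretion_color,LLL,8
S1,CF,A,mucus_plugging,RUL,0
S1,CF,A,mucus_plugging,RML,0
S1,CF,A,mucus_plugging,RLL,0
S1,CF,A,mucus_plugging,LUL,0
S1,CF,A,mucus_plugging,LLL,0
S1,CF,B,mucus_plugging,RUL,0
S1,CF,B,mucus_plugging,RML,0
S1,CF,B,mucus_plugging,RLL,0
S1,CF,B,mucus_plugging,LUL,0
S1,CF,B,mucus_plugging,LLL,0
S2,CF,A,mucus_plugging,RUL,1
S2,CF,A,mucus_plugging,RML,0
S2,CF,A,mucus_plugging,RLL,0
S2,CF,A,mucus_plugging,LUL,0
S2,CF,A,mucus_plugging,LLL,0
S2,CF,B,mucus_plugging,RUL,1
S2,CF,B,mucus_plugging,RML,1
S2,CF,B,mucus_plugging,RLL,1
S2,CF,B,mucus_plugging,LUL,0
S2,CF,B,mucus_plugging,LLL,0
S3,nonCF,A,mucus_plugging,RUL,1
S3,nonCF,A,mucus_plugging,RML,1
S3,nonCF,A,mucus_plugging,RLL,1
S3,nonCF,A,mucus_plugging,LUL,1
S3,nonCF,A,mucus_plugging,LLL,0
S3,nonCF,B,mucus_plugging,RUL,1
S3,nonCF,B,mucus_plugging,RML,1
S3,nonCF,B,mucus_plugging,RLL,1
S3,nonCF,B,mucus_plugging,LUL,0
S3,nonCF,B,mucus_plugging,LLL,0
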