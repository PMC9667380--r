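comparison,period,effect_kind,delta_cost,delta_effect,printed_icer
2v1,3,madrs,-19,4,dominant
2v1,6,madrs,-1300,5.5,dominant
2v1,9,madrs,-879,3.6,dominant
2v1,12,madrs,-659,3.8,dominant
2v1,total_3_12,madrs,-2858,3.8,dominant
3v1,3,madrs,113,1.1,103
3v1,6,madrs,-348,4.8,dominant
3v1,9,madrs,-601,2.5,dominant
3v1,12,madrs,743,3.6,206
3v1,total_3_12,madrs,-94,3.6,dominant
2v3,3,madrs,581,-1.9,dominated
2v3,6,madrs,4339,-1.1,dominated
2v3,9,madrs,466,0.3,1553
2v3,12,madrs,2423,0.7,3461
2v3,total_3_12,madrs,7798,0.7,11140
2v1,3,qaly,-19,0.0005,NA
2v1,6,qaly,-1300,0.003,NA
2v1,9,qaly,-879,0.004,NA
2v1,12,qaly,-659,0.004,NA
2v1,total_3_12,qaly,-2858,0.012,dominant
3v1,3,qaly,113,0.0007,NA
3v1,6,qaly,-348,0.002,NA
3v1,9,qaly,-601,-0.0005,NA
3v1,12,qaly,743,-0.0004,NA
3v1,total_3_12,qaly,-94,0.002,dominant
2v3,3,qaly,581,0.002,NA
2v3,6,qaly,4339,0.004,NA
2v3,9,qaly,466,-0.006,NA
2v3,12,qaly,2423,-0.003,NA
2v3,total_3_12,qaly,7798,-0.004,dominated
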