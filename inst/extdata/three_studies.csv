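label,study,format,p1,n21,n11,n22,n12,dq_yes,dq_no
Drug use1-Q1,I,question,0.2,249,112,150,223,NA,NA
Drug use1-Q2,I,question,0.2,188,185,183,178,NA,NA
Drug use1-Q3,I,question,0.2,197,164,174,199,NA,NA
Drug use1-Q4,I,question,0.2,275,98,120,241,NA,NA
Drug use1-S1,I,statement,0.2,233,143,166,229,NA,NA
Drug use1-S2,I,statement,0.2,197,198,171,205,NA,NA
Drug use1-S3,I,statement,0.2,187,189,208,187,NA,NA
Drug use1-S4,I,statement,0.2,304,91,120,256,NA,NA
Covid-F1,II,factual,0.2,249,145,186,247,37,341
Covid-F2,II,factual,0.2,284,149,164,230,52,326
Covid-F3,II,factual,0.2,233,161,181,252,128,250
Covid-F4,II,factual,0.2,271,162,146,248,65,313
Covid-J1,II,judgmental,0.2,262,158,149,225,44,359
Covid-J2,II,judgmental,0.2,233,141,154,266,53,350
Covid-J3,II,judgmental,0.2,237,183,151,223,103,300
Covid-J4,II,judgmental,0.2,210,164,155,265,28,375
Drug use2-Q1,III,question,0.2,438,163,232,378,121,469
Drug use2-Q2,III,question,0.2,330,280,285,316,274,316
Drug use2-Q3,III,question,0.2,302,299,300,310,230,360
Drug use2-Q4,III,question,0.2,478,132,138,463,26,564
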