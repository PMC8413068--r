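Subject,Age,Gender,Number of subtractions,Count quality
Subject00,20,M,27,1
Subject01,19,F,17,1
Subject02,17,M,22,1
Subject03,23,F,28,1
Subject04,17,F,21,1
Subject05,18,F,15,1
Subject06,23,M,16,1
Subject07,22,F,24,1
Subject08,16,F,25,1
Subject09,20,F,28,1
Subject10,25,F,6,0
Subject11,17,F,24,1
Subject12,21,M,23,1
Subject13,21,F,16,1
Subject14,17,M,3,0
Subject15,19,F,5,0
Subject16,18,F,17,1
Subject17,21,M,20,1
Subject18,20,F,6,0
Subject19,17,M,2,0
Subject20,22,F,20,1
Subject21,21,M,15,1
Subject22,25,F,4,0
Subject23,25,M,27,1
Subject24,23,F,18,1
Subject25,20,F,24,1
Subject26,16,M,24,1
Subject27,16,M,7,0
Subject28,22,M,15,1
Subject29,19,F,31,1
Subject30,25,M,7,0
Subject31,24,F,25,1
Subject32,19,F,16,1
Subject33,24,F,4,0
Subject34,26,F,7,0
Subject35,18,M,19,1
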