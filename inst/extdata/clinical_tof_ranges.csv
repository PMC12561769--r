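case,position,d_real_mm,d_tof_mm
brain,a,94.7,93.97
brain,b,111.14,112.97
brain,c,141.03,249.15
brain,d,116.5,171.678
brain,e,74.65,91.19
head_neck,a,104.66,189.52
head_neck,b,99.02,112.76
head_neck,c,93.01,130.86
head_neck,d,100.22,115.15
head_neck,e,72.8,103.34
liver,a,130.6,143.14
liver,b,134.62,107.94
liver,c,215.18,296.83
liver,d,265.19,282.79
liver,e,282.18,331.46
prostate,a,163.03,202.09
prostate,b,121.02,117.63
prostate,c,127.26,90.35
prostate,d,132.97,121.63
prostate,e,130.38,172.1
lung,a,130,95.71
lung,b,143.69,175.28
lung,c,241.05,322.37
lung,d,252.56,444.95
lung,e,182.22,245.62
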