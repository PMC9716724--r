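# Fragment-size age calibration for wild giant pandas (Qinling).
# Mean bamboo-leaf fragment length/width (mm) per reference individual with
# a known or field-assigned age class. Adults are known-age reference
# animals; the sub-adult rows are field-classified animals included so that
# both class centroids are defined.
individual,lengthMean,widthMean,ageClass
XiYue,33.181,8.170,adult
DianDian,33.523,8.083,adult
ZhenZhen,25.276,6.764,adult
HuZi,23.462,8.890,adult
NiuNiu,29.141,7.971,adult
LanNi,23.732,7.488,adult
LiLi,22.879,7.442,subadult
WFG,22.090,8.122,subadult
HNB,18.666,6.089,subadult
JJG,21.270,7.601,subadult
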