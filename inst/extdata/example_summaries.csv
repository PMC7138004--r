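analyte,approach,source,u_bias,cv_wl
CA 19-9,nordtest,pt,9.1,9.2
CA 19-9,nordtest,crc,2.4,9.2
CA 19-9,eurolab,pt,9.5,9.2
CA 19-9,eurolab,crc,2.4,9.2
CA 19-9,cofrac,pt,18.0,9.2
Testosterone,nordtest,pt,6.6,6.3
Testosterone,nordtest,crc,7.9,6.3
Testosterone,eurolab,pt,6.9,6.3
Testosterone,eurolab,crc,7.9,6.3
Testosterone,cofrac,pt,9.5,6.3
ALP,nordtest,pt,3.9,4.1
ALP,nordtest,crc,2.2,4.1
ALP,nordtest,iqcs,3.3,4.1
ALP,eurolab,pt,9.6,4.1
ALP,eurolab,crc,2.2,4.1
ALP,cofrac,pt,4.7,4.1
ALP,cofrac,iqcs,4.9,4.1
Creatinine,nordtest,pt,5.3,2.0
Creatinine,nordtest,crc,3.7,2.0
Creatinine,nordtest,iqcs,2.9,2.0
Creatinine,eurolab,pt,8.6,2.0
Creatinine,eurolab,crc,3.7,2.0
Creatinine,cofrac,pt,9.1,2.0
Creatinine,cofrac,iqcs,4.4,2.0
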