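label,analyte_class,mean,p95
Jilin,SCCP,27.0,92.2
Heilongjiang,SCCP,10.7,33.7
Hebei,SCCP,29.7,97.4
Tianjin,SCCP,15.6,42.1
Beijing,SCCP,17.9,53.1
Shandong,SCCP,6.9,21.3
Jiangxi,SCCP,8.8,33.1
Jiangsu,SCCP,159.1,485.6
Jilin,MCCP,68.8,225.3
Heilongjiang,MCCP,36.5,78.2
Hebei,MCCP,75.3,241.1
Tianjin,MCCP,7.6,20.3
Beijing,MCCP,13.7,41.2
Shandong,MCCP,16.6,50.9
Jiangxi,MCCP,17.1,53.9
Jiangsu,MCCP,84.4,261.7
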