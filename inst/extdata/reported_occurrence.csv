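region,analyte_class,n,mean,min,max
Jilin,SCCP,45,99.7,26.6,470.2
Heilongjiang,SCCP,20,35.0,16.7,82.3
Hebei,SCCP,15,102.7,9.5,374.8
Tianjin,SCCP,7,42.6,23.0,63.3
Beijing,SCCP,10,51.2,16.8,135.5
Shandong,SCCP,10,21.5,14.4,30.6
Jiangxi,SCCP,11,30.4,12.2,125.9
Jiangsu,SCCP,8,497.6,32.1,1542.4
Jilin,MCCP,45,228.4,86.3,910.7
Heilongjiang,MCCP,20,77.6,20.8,161.6
Hebei,MCCP,15,246.4,32.8,1517.9
Tianjin,MCCP,7,29.9,20.0,57.6
Beijing,MCCP,10,44.3,20.5,94.5
Shandong,MCCP,10,52.0,29.7,73.6
Jiangxi,MCCP,11,58.3,23.4,136.7
Jiangsu,MCCP,8,299.2,49.3,990.8
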