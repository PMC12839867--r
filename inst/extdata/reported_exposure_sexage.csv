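label,analyte_class,mean,p95
3-6,SCCP,89.0,275.2
7-12,SCCP,66.2,206.7
13-17 male,SCCP,39.8,122.6
13-17 female,SCCP,49.1,150.0
18-59 male,SCCP,30.2,91.8
18-59 female,SCCP,30.6,92.1
>=60 male,SCCP,22.5,70.0
>=60 female,SCCP,22.3,68.3
Consumer only,SCCP,93.9,290.7
All,SCCP,32.8,106.4
3-6,MCCP,132.6,412.0
7-12,MCCP,99.4,313.4
13-17 male,MCCP,59.6,183.0
13-17 female,MCCP,73.1,222.7
18-59 male,MCCP,45.2,137.5
18-59 female,MCCP,45.5,137.6
>=60 male,MCCP,33.5,101.7
>=60 female,MCCP,33.2,100.8
Consumer only,MCCP,153.2,450.9
All,MCCP,52.6,159.8
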