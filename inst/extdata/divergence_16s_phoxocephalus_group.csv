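"group","n","atillo","atratus","chomskyi","gloria","hampatusami","jimenezi","lutzae","multicolor","phoxocephalus","teslai","tinguichaca","torresi","totoroi","verrucolatus","versicolor","CCS1","CCS2","UCS1","UCS2","UCS3"
"atillo",18,"0.0","0.9","0.9","0.7","0.9","1.0","0.8","0.9","1.0","0.6","0.8","1.0","0.9","0.8","0.7","0.8","0.8","0.5","0.7","0.9"
"atratus",2,"7.3","0.0","0.7","0.8","1.0","0.7","0.8","0.8","0.8","1.0","1.0","0.9","0.7","0.6","0.8","0.7","0.7","0.9","1.0","1.0"
"chomskyi",2,"7.1","5.4","0.2±0.1","0.7","1.0","0.7","0.7","0.8","0.8","1.0","1.0","0.9","0.7","0.7","0.7","0.7","0.7","0.9","1.0","1.0"
"gloria",5,"5.1","5.8","6.3","0.7±0.2","0.9","0.7","0.6","0.8","0.8","0.8","0.9","0.9","0.7","0.7","0.7","0.7","0.4","0.8","0.9","0.9"
"hampatusami",1,"7.0","11.1","10.9","8.7","NA","1.0","0.9","1.0","1.0","1.0","0.9","1.0","1.0","0.9","0.9","1.0","0.9","1.0","1.1","0.7"
"jimenezi",4,"7.7","6.8","7.8","5.8","10.7","0.5±0.2","0.7","1.0","0.9","1.0","1.0","0.9","0.8","0.6","0.7","0.7","0.6","1.0","1.1","1.0"
"lutzae",9,"5.0","5.7","5.6","2.9","7.5","5.3","0.2±0.1","0.9","0.8","0.8","0.8","0.9","0.7","0.6","0.7","0.7","0.6","0.8","0.9","0.9"
"multicolor",2,"6.7","4.4","4.9","5.5","8.9","6.7","5.5","0.0","0.9","1.0","1.0","1.0","0.9","0.9","1.0","0.9","0.8","1.0","1.0","1.0"
"phoxocephalus",1,"7.8","5.8","6.7","5.4","11.1","6.8","5.8","6.3","NA","1.1","1.0","1.0","0.7","0.8","0.9","0.8","0.9","1.0","1.1","1.0"
"teslai",1,"2.6","7.6","7.4","5.9","7.6","7.9","5.2","7.1","8.0","NA","0.9","1.0","1.0","0.8","0.8","0.8","0.9","0.6","0.6","1.0"
"tinguichaca",10,"4.7","7.8","7.7","6.1","7.0","7.8","5.3","7.5","7.7","5.7","0.0","1.0","0.9","0.8","0.8","0.8","0.9","0.8","0.9","0.9"
"torresi",2,"8.7","8.7","9.5","7.3","11.1","9.1","7.5","8.3","8.6","9.1","8.6","0.9±0.4","0.9","0.9","0.8","0.9","0.8","1.0","1.1","1.1"
"totoroi",3,"7.0","6.0","6.8","6.0","11.1","6.9","5.5","6.4","5.9","7.4","7.2","8.0","1.0±0.2","0.7","0.7","0.8","0.7","0.9","0.9","0.9"
"verrucolatus",5,"4.6","5.4","6.6","4.8","9.7","5.6","4.3","6.0","6.1","4.9","4.9","8.6","5.7","0.2±0.1","0.6","0.5","0.6","0.8","0.8","0.9"
"versicolor",3,"3.9","7.2","7.4","6.0","10.2","7.5","5.6","7.9","8.1","4.4","5.8","8.7","7.1","4.7","0.4±0.1","0.6","0.6","0.7","0.8","1.0"
"CCS1",1,"4.4","6.2","7.2","5.3","10.4","6.4","5.1","6.9","6.8","4.7","4.6","8.6","6.1","3.2","5.0","NA","0.6","0.8","0.9","0.9"
"CCS2",2,"5.4","5.8","6.0","2.0","7.5","5.8","2.9","5.4","6.0","6.4","5.8","7.6","5.9","4.5","5.7","5.1","0.2±0.1","0.8","0.9","0.9"
"UCS1",1,"2.5","7.0","7.2","5.4","7.4","7.5","5.1","6.5","7.3","3.0","5.6","8.6","7.4","4.3","2.9","4.8","5.8","NA","0.6","0.9"
"UCS2",1,"3.2","7.7","7.3","6.3","8.0","8.4","5.9","6.9","8.1","2.5","5.8","9.9","7.4","4.9","4.3","4.8","6.6","2.8","NA","1.0"
"UCS3",1,"6.9","8.1","7.4","6.6","3.5","7.3","6.2","8.0","7.7","7.1","6.5","8.5","7.7","6.9","7.5","6.7","6.8","7.2","7.7","NA"
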