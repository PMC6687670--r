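"group","n","cryptomelas","gagliardoi","muscosus","nangaritza","spinosus"
"cryptomelas",2,"0.0","1.1","0.8","0.9","0.6"
"gagliardoi",2,"8.8","0.9±0.4","1.1","1.1","1.0"
"muscosus",1,"7.6","8.6","NA","1.0","0.7"
"nangaritza",1,"8.1","8.3","9.8","NA","0.9"
"spinosus",1,"5.9","7.6","7.4","8.1","NA"
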