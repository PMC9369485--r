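"response","contaminant","sorbent","index","printed_pct"
"Org","Cu","Control","IF_HM",-13.7
"Org","Zn","Control","IF_HM",-20.5
"Act","Cu","Control","IF_HM",-2.1
"Act","Ni","Control","IF_HM",-2.1
"Act","Zn","Control","IF_HM",-35.4
"Fun","Ni","Control","IF_HM",-3.6
"Fun","Cu","Control","IF_HM",-10.9
"Org","Ni","Molecular sieve","IF_Ad",52.4
"Act","Ni","Molecular sieve","IF_Ad",67.6
"Fun","Ni","Molecular sieve","IF_Ad",56.1
"Org","Zn","Zeolite","IF_Ad",69
"Act","Zn","Zeolite","IF_Ad",210.4
"Fun","Zn","Zeolite","IF_Ad",13.31
"Shoots","Ni","Control","IF_HM",-53.6
"Roots","Ni","Control","IF_HM",-45.7
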