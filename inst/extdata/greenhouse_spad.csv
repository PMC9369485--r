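"contaminant","sorbent","replicate","response","value"
"C0","Control",1,"SPAD",35.99
"C0","Molecular sieve",1,"SPAD",34.71
"C0","Halloysite",1,"SPAD",38.64
"C0","Sepiolite",1,"SPAD",35.18
"C0","Expanded clay",1,"SPAD",35.24
"C0","Biochar",1,"SPAD",39.14
"C0","Zeolite",1,"SPAD",33.49
"Cu","Control",1,"SPAD",35.63
"Cu","Molecular sieve",1,"SPAD",33.88
"Cu","Halloysite",1,"SPAD",36.01
"Cu","Sepiolite",1,"SPAD",37.53
"Cu","Expanded clay",1,"SPAD",36.95
"Cu","Biochar",1,"SPAD",32.78
"Cu","Zeolite",1,"SPAD",32.9
"Ni","Control",1,"SPAD",21.88
"Ni","Molecular sieve",1,"SPAD",33.15
"Ni","Halloysite",1,"SPAD",27.46
"Ni","Sepiolite",1,"SPAD",34.15
"Ni","Expanded clay",1,"SPAD",21.34
"Ni","Biochar",1,"SPAD",32.73
"Ni","Zeolite",1,"SPAD",32.55
"Zn","Control",1,"SPAD",34.14
"Zn","Molecular sieve",1,"SPAD",35.56
"Zn","Halloysite",1,"SPAD",38.63
"Zn","Sepiolite",1,"SPAD",36.83
"Zn","Expanded clay",1,"SPAD",36.76
"Zn","Biochar",1,"SPAD",37.31
"Zn","Zeolite",1,"SPAD",38.21
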