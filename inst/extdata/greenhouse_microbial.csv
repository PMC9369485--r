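"contaminant","sorbent","replicate","response","value"
"C0","Control",1,"Org",30.62
"C0","Molecular sieve",1,"Org",41.61
"C0","Halloysite",1,"Org",32.78
"C0","Sepiolite",1,"Org",33.03
"C0","Expanded clay",1,"Org",34.41
"C0","Biochar",1,"Org",38.21
"C0","Zeolite",1,"Org",32.93
"Cu","Control",1,"Org",26.42
"Cu","Molecular sieve",1,"Org",33.38
"Cu","Halloysite",1,"Org",28.84
"Cu","Sepiolite",1,"Org",26.42
"Cu","Expanded clay",1,"Org",24.21
"Cu","Biochar",1,"Org",27.31
"Cu","Zeolite",1,"Org",27.61
"Ni","Control",1,"Org",24.85
"Ni","Molecular sieve",1,"Org",37.86
"Ni","Halloysite",1,"Org",30.76
"Ni","Sepiolite",1,"Org",34.76
"Ni","Expanded clay",1,"Org",33.38
"Ni","Biochar",1,"Org",32.14
"Ni","Zeolite",1,"Org",17.45
"Zn","Control",1,"Org",24.35
"Zn","Molecular sieve",1,"Org",27.02
"Zn","Halloysite",1,"Org",25.88
"Zn","Sepiolite",1,"Org",25.59
"Zn","Expanded clay",1,"Org",20.61
"Zn","Biochar",1,"Org",21.4
"Zn","Zeolite",1,"Org",41.17
"C0","Control",1,"Act",16.17
"C0","Molecular sieve",1,"Act",17.35
"C0","Halloysite",1,"Act",20.41
"C0","Sepiolite",1,"Act",20.85
"C0","Expanded clay",1,"Act",22.53
"C0","Biochar",1,"Act",19.28
"C0","Zeolite",1,"Act",14.1
"Cu","Control",1,"Act",15.83
"Cu","Molecular sieve",1,"Act",18.39
"Cu","Halloysite",1,"Act",27.02
"Cu","Sepiolite",1,"Act",24.75
"Cu","Expanded clay",1,"Act",16.91
"Cu","Biochar",1,"Act",20.21
"Cu","Zeolite",1,"Act",18.59
"Ni","Control",1,"Act",15.83
"Ni","Molecular sieve",1,"Act",26.52
"Ni","Halloysite",1,"Act",15.09
"Ni","Sepiolite",1,"Act",17.8
"Ni","Expanded clay",1,"Act",16.12
"Ni","Biochar",1,"Act",19.28
"Ni","Zeolite",1,"Act",20.85
"Zn","Control",1,"Act",10.45
"Zn","Molecular sieve",1,"Act",17.99
"Zn","Halloysite",1,"Act",16.91
"Zn","Sepiolite",1,"Act",11.49
"Zn","Expanded clay",1,"Act",7.74
"Zn","Biochar",1,"Act",13.16
"Zn","Zeolite",1,"Act",32.44
"C0","Control",1,"Fun",6.75
"C0","Molecular sieve",1,"Fun",7.59
"C0","Halloysite",1,"Fun",9.71
"C0","Sepiolite",1,"Fun",7.1
"C0","Expanded clay",1,"Fun",10.3
"C0","Biochar",1,"Fun",10.6
"C0","Zeolite",1,"Fun",8.97
"Cu","Control",1,"Fun",6.01
"Cu","Molecular sieve",1,"Fun",6.56
"Cu","Halloysite",1,"Fun",7.39
"Cu","Sepiolite",1,"Fun",7.3
"Cu","Expanded clay",1,"Fun",9.66
"Cu","Biochar",1,"Fun",5.42
"Cu","Zeolite",1,"Fun",8.28
"Ni","Control",1,"Fun",6.51
"Ni","Molecular sieve",1,"Fun",10.16
"Ni","Halloysite",1,"Fun",4.14
"Ni","Sepiolite",1,"Fun",9.86
"Ni","Expanded clay",1,"Fun",10.06
"Ni","Biochar",1,"Fun",6.01
"Ni","Zeolite",1,"Fun",6.06
"Zn","Control",1,"Fun",6.31
"Zn","Molecular sieve",1,"Fun",6.36
"Zn","Halloysite",1,"Fun",4.98
"Zn","Sepiolite",1,"Fun",6.66
"Zn","Expanded clay",1,"Fun",7.15
"Zn","Biochar",1,"Fun",6.66
"Zn","Zeolite",1,"Fun",7.15
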