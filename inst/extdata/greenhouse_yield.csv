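"contaminant","sorbent","replicate","response","value"
"C0","Control",1,"Shoots",25.27
"C0","Molecular sieve",1,"Shoots",27.26
"C0","Halloysite",1,"Shoots",27.66
"C0","Sepiolite",1,"Shoots",27.04
"C0","Expanded clay",1,"Shoots",26.36
"C0","Biochar",1,"Shoots",29.89
"C0","Zeolite",1,"Shoots",29.06
"Cu","Control",1,"Shoots",25.29
"Cu","Molecular sieve",1,"Shoots",26.41
"Cu","Halloysite",1,"Shoots",27.46
"Cu","Sepiolite",1,"Shoots",29.75
"Cu","Expanded clay",1,"Shoots",28.82
"Cu","Biochar",1,"Shoots",28.88
"Cu","Zeolite",1,"Shoots",28.49
"Ni","Control",1,"Shoots",11.72
"Ni","Molecular sieve",1,"Shoots",29.76
"Ni","Halloysite",1,"Shoots",17.23
"Ni","Sepiolite",1,"Shoots",27.11
"Ni","Expanded clay",1,"Shoots",13.35
"Ni","Biochar",1,"Shoots",23.21
"Ni","Zeolite",1,"Shoots",22.99
"Zn","Control",1,"Shoots",27.52
"Zn","Molecular sieve",1,"Shoots",28.31
"Zn","Halloysite",1,"Shoots",29.29
"Zn","Sepiolite",1,"Shoots",28.19
"Zn","Expanded clay",1,"Shoots",27.81
"Zn","Biochar",1,"Shoots",29.71
"Zn","Zeolite",1,"Shoots",26.91
"C0","Control",1,"Roots",5.18
"C0","Molecular sieve",1,"Roots",5.89
"C0","Halloysite",1,"Roots",7.63
"C0","Sepiolite",1,"Roots",6.06
"C0","Expanded clay",1,"Roots",5.63
"C0","Biochar",1,"Roots",5.8
"C0","Zeolite",1,"Roots",7.15
"Cu","Control",1,"Roots",4.72
"Cu","Molecular sieve",1,"Roots",4.84
"Cu","Halloysite",1,"Roots",7.22
"Cu","Sepiolite",1,"Roots",5.02
"Cu","Expanded clay",1,"Roots",5.31
"Cu","Biochar",1,"Roots",5.55
"Cu","Zeolite",1,"Roots",7.49
"Ni","Control",1,"Roots",2.81
"Ni","Molecular sieve",1,"Roots",5.78
"Ni","Halloysite",1,"Roots",2.98
"Ni","Sepiolite",1,"Roots",4.13
"Ni","Expanded clay",1,"Roots",3.03
"Ni","Biochar",1,"Roots",3.01
"Ni","Zeolite",1,"Roots",3.3
"Zn","Control",1,"Roots",6.32
"Zn","Molecular sieve",1,"Roots",8
"Zn","Halloysite",1,"Roots",7.7
"Zn","Sepiolite",1,"Roots",9.66
"Zn","Expanded clay",1,"Roots",6.44
"Zn","Biochar",1,"Roots",6.89
"Zn","Zeolite",1,"Roots",8.14
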