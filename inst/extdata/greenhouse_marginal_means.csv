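"family","response","margin","level","printed"
"microbial","Org","sorbent","Control",26.56
"microbial","Org","sorbent","Molecular sieve",34.97
"microbial","Org","sorbent","Halloysite",29.57
"microbial","Org","sorbent","Sepiolite",29.95
"microbial","Org","sorbent","Expanded clay",28.15
"microbial","Org","sorbent","Biochar",29.76
"microbial","Org","sorbent","Zeolite",29.79
"microbial","Org","contaminant","C0",34.8
"microbial","Org","contaminant","Cu",27.74
"microbial","Org","contaminant","Ni",30.17
"microbial","Org","contaminant","Zn",26.57
"microbial","Act","sorbent","Control",14.57
"microbial","Act","sorbent","Molecular sieve",20.07
"microbial","Act","sorbent","Halloysite",19.86
"microbial","Act","sorbent","Sepiolite",18.72
"microbial","Act","sorbent","Expanded clay",15.83
"microbial","Act","sorbent","Biochar",17.98
"microbial","Act","sorbent","Zeolite",21.49
"microbial","Act","contaminant","C0",18.67
"microbial","Act","contaminant","Cu",20.24
"microbial","Act","contaminant","Ni",18.78
"microbial","Act","contaminant","Zn",15.74
"microbial","Fun","sorbent","Control",6.4
"microbial","Fun","sorbent","Molecular sieve",7.67
"microbial","Fun","sorbent","Halloysite",6.56
"microbial","Fun","sorbent","Sepiolite",7.73
"microbial","Fun","sorbent","Expanded clay",9.29
"microbial","Fun","sorbent","Biochar",7.17
"microbial","Fun","sorbent","Zeolite",7.62
"microbial","Fun","contaminant","C0",8.72
"microbial","Fun","contaminant","Cu",7.23
"microbial","Fun","contaminant","Ni",7.54
"microbial","Fun","contaminant","Zn",6.47
"enzymes","Deh","sorbent","Control",3.994
"enzymes","Deh","sorbent","Molecular sieve",6.32
"enzymes","Deh","sorbent","Halloysite",4.656
"enzymes","Deh","sorbent","Sepiolite",4.625
"enzymes","Deh","sorbent","Expanded clay",5.144
"enzymes","Deh","sorbent","Biochar",4.775
"enzymes","Deh","sorbent","Zeolite",5.993
"enzymes","Deh","contaminant","C0",7.547
"enzymes","Deh","contaminant","Cu",3.556
"enzymes","Deh","contaminant","Ni",2.52
"enzymes","Deh","contaminant","Zn",6.667
"enzymes","Cat","sorbent","Control",0.292
"enzymes","Cat","sorbent","Molecular sieve",0.344
"enzymes","Cat","sorbent","Halloysite",0.348
"enzymes","Cat","sorbent","Sepiolite",0.322
"enzymes","Cat","sorbent","Expanded clay",0.322
"enzymes","Cat","sorbent","Biochar",0.367
"enzymes","Cat","sorbent","Zeolite",0.337
"enzymes","Cat","contaminant","C0",0.358
"enzymes","Cat","contaminant","Cu",0.318
"enzymes","Cat","contaminant","Ni",0.321
"enzymes","Cat","contaminant","Zn",0.337
"enzymes","Ure","sorbent","Control",0.202
"enzymes","Ure","sorbent","Molecular sieve",0.246
"enzymes","Ure","sorbent","Halloysite",0.223
"enzymes","Ure","sorbent","Sepiolite",0.229
"enzymes","Ure","sorbent","Expanded clay",0.246
"enzymes","Ure","sorbent","Biochar",0.243
"enzymes","Ure","sorbent","Zeolite",0.246
"enzymes","Ure","contaminant","C0",0.25
"enzymes","Ure","contaminant","Cu",0.232
"enzymes","Ure","contaminant","Ni",0.207
"enzymes","Ure","contaminant","Zn",0.246
"enzymes","Pac","sorbent","Control",1.139
"enzymes","Pac","sorbent","Molecular sieve",1.343
"enzymes","Pac","sorbent","Halloysite",1.296
"enzymes","Pac","sorbent","Sepiolite",1.422
"enzymes","Pac","sorbent","Expanded clay",1.375
"enzymes","Pac","sorbent","Biochar",1.361
"enzymes","Pac","sorbent","Zeolite",1.462
"enzymes","Pac","contaminant","C0",1.544
"enzymes","Pac","contaminant","Cu",1.025
"enzymes","Pac","contaminant","Ni",1.345
"enzymes","Pac","contaminant","Zn",1.457
"enzymes","Pal","sorbent","Control",1.121
"enzymes","Pal","sorbent","Molecular sieve",1.256
"enzymes","Pal","sorbent","Halloysite",1.212
"enzymes","Pal","sorbent","Sepiolite",1.34
"enzymes","Pal","sorbent","Expanded clay",1.208
"enzymes","Pal","sorbent","Biochar",1.226
"enzymes","Pal","sorbent","Zeolite",1.249
"enzymes","Pal","contaminant","C0",1.468
"enzymes","Pal","contaminant","Cu",1.082
"enzymes","Pal","contaminant","Ni",1.115
"enzymes","Pal","contaminant","Zn",1.255
"enzymes","Aryl","sorbent","Control",0.176
"enzymes","Aryl","sorbent","Molecular sieve",0.207
"enzymes","Aryl","sorbent","Halloysite",0.2
"enzymes","Aryl","sorbent","Sepiolite",0.192
"enzymes","Aryl","sorbent","Expanded clay",0.194
"enzymes","Aryl","sorbent","Biochar",0.192
"enzymes","Aryl","sorbent","Zeolite",0.21
"enzymes","Aryl","contaminant","C0",0.207
"enzymes","Aryl","contaminant","Cu",0.194
"enzymes","Aryl","contaminant","Ni",0.191
"enzymes","Aryl","contaminant","Zn",0.191
"enzymes","Glu","sorbent","Control",0.564
"enzymes","Glu","sorbent","Molecular sieve",0.66
"enzymes","Glu","sorbent","Halloysite",0.68
"enzymes","Glu","sorbent","Sepiolite",0.657
"enzymes","Glu","sorbent","Expanded clay",0.666
"enzymes","Glu","sorbent","Biochar",0.676
"enzymes","Glu","sorbent","Zeolite",0.718
"enzymes","Glu","contaminant","C0",0.681
"enzymes","Glu","contaminant","Cu",0.602
"enzymes","Glu","contaminant","Ni",0.632
"enzymes","Glu","contaminant","Zn",0.725
"yield","Shoots","sorbent","Control",22.45
"yield","Shoots","sorbent","Molecular sieve",27.93
"yield","Shoots","sorbent","Halloysite",25.41
"yield","Shoots","sorbent","Sepiolite",28.02
"yield","Shoots","sorbent","Expanded clay",24.08
"yield","Shoots","sorbent","Biochar",27.92
"yield","Shoots","sorbent","Zeolite",26.86
"yield","Shoots","contaminant","C0",27.51
"yield","Shoots","contaminant","Cu",27.87
"yield","Shoots","contaminant","Ni",20.77
"yield","Shoots","contaminant","Zn",28.25
"yield","Roots","sorbent","Control",4.76
"yield","Roots","sorbent","Molecular sieve",6.13
"yield","Roots","sorbent","Halloysite",6.38
"yield","Roots","sorbent","Sepiolite",6.22
"yield","Roots","sorbent","Expanded clay",5.1
"yield","Roots","sorbent","Biochar",5.31
"yield","Roots","sorbent","Zeolite",6.52
"yield","Roots","contaminant","C0",6.19
"yield","Roots","contaminant","Cu",5.74
"yield","Roots","contaminant","Ni",3.58
"yield","Roots","contaminant","Zn",7.59
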