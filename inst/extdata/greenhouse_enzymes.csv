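"contaminant","sorbent","replicate","response","value"
"C0","Control",1,"Deh",6.231
"C0","Molecular sieve",1,"Deh",9.134
"C0","Halloysite",1,"Deh",6.502
"C0","Sepiolite",1,"Deh",6.564
"C0","Expanded clay",1,"Deh",7.776
"C0","Biochar",1,"Deh",6.927
"C0","Zeolite",1,"Deh",9.694
"Cu","Control",1,"Deh",2.632
"Cu","Molecular sieve",1,"Deh",4.329
"Cu","Halloysite",1,"Deh",3.26
"Cu","Sepiolite",1,"Deh",3.243
"Cu","Expanded clay",1,"Deh",3.854
"Cu","Biochar",1,"Deh",3.243
"Cu","Zeolite",1,"Deh",4.329
"Ni","Control",1,"Deh",1.273
"Ni","Molecular sieve",1,"Deh",4.041
"Ni","Halloysite",1,"Deh",2.733
"Ni","Sepiolite",1,"Deh",2.377
"Ni","Expanded clay",1,"Deh",2.207
"Ni","Biochar",1,"Deh",2.156
"Ni","Zeolite",1,"Deh",2.852
"Zn","Control",1,"Deh",5.84
"Zn","Molecular sieve",1,"Deh",7.776
"Zn","Halloysite",1,"Deh",6.129
"Zn","Sepiolite",1,"Deh",6.316
"Zn","Expanded clay",1,"Deh",6.74
"Zn","Biochar",1,"Deh",6.774
"Zn","Zeolite",1,"Deh",7.097
"C0","Control",1,"Cat",0.338
"C0","Molecular sieve",1,"Cat",0.357
"C0","Halloysite",1,"Cat",0.364
"C0","Sepiolite",1,"Cat",0.349
"C0","Expanded clay",1,"Cat",0.342
"C0","Biochar",1,"Cat",0.379
"C0","Zeolite",1,"Cat",0.375
"Cu","Control",1,"Cat",0.233
"Cu","Molecular sieve",1,"Cat",0.349
"Cu","Halloysite",1,"Cat",0.353
"Cu","Sepiolite",1,"Cat",0.259
"Cu","Expanded clay",1,"Cat",0.334
"Cu","Biochar",1,"Cat",0.364
"Cu","Zeolite",1,"Cat",0.33
"Ni","Control",1,"Cat",0.289
"Ni","Molecular sieve",1,"Cat",0.319
"Ni","Halloysite",1,"Cat",0.334
"Ni","Sepiolite",1,"Cat",0.342
"Ni","Expanded clay",1,"Cat",0.304
"Ni","Biochar",1,"Cat",0.353
"Ni","Zeolite",1,"Cat",0.304
"Zn","Control",1,"Cat",0.308
"Zn","Molecular sieve",1,"Cat",0.353
"Zn","Halloysite",1,"Cat",0.342
"Zn","Sepiolite",1,"Cat",0.338
"Zn","Expanded clay",1,"Cat",0.308
"Zn","Biochar",1,"Cat",0.372
"Zn","Zeolite",1,"Cat",0.338
"C0","Control",1,"Ure",0.223
"C0","Molecular sieve",1,"Ure",0.254
"C0","Halloysite",1,"Ure",0.239
"C0","Sepiolite",1,"Ure",0.239
"C0","Expanded clay",1,"Ure",0.254
"C0","Biochar",1,"Ure",0.262
"C0","Zeolite",1,"Ure",0.277
"Cu","Control",1,"Ure",0.208
"Cu","Molecular sieve",1,"Ure",0.239
"Cu","Halloysite",1,"Ure",0.223
"Cu","Sepiolite",1,"Ure",0.231
"Cu","Expanded clay",1,"Ure",0.231
"Cu","Biochar",1,"Ure",0.231
"Cu","Zeolite",1,"Ure",0.262
"Ni","Control",1,"Ure",0.162
"Ni","Molecular sieve",1,"Ure",0.246
"Ni","Halloysite",1,"Ure",0.177
"Ni","Sepiolite",1,"Ure",0.216
"Ni","Expanded clay",1,"Ure",0.246
"Ni","Biochar",1,"Ure",0.185
"Ni","Zeolite",1,"Ure",0.216
"Zn","Control",1,"Ure",0.216
"Zn","Molecular sieve",1,"Ure",0.246
"Zn","Halloysite",1,"Ure",0.254
"Zn","Sepiolite",1,"Ure",0.231
"Zn","Expanded clay",1,"Ure",0.254
"Zn","Biochar",1,"Ure",0.293
"Zn","Zeolite",1,"Ure",0.231
"C0","Control",1,"Pac",1.275
"C0","Molecular sieve",1,"Pac",1.593
"C0","Halloysite",1,"Pac",1.483
"C0","Sepiolite",1,"Pac",1.755
"C0","Expanded clay",1,"Pac",1.533
"C0","Biochar",1,"Pac",1.567
"C0","Zeolite",1,"Pac",1.599
"Cu","Control",1,"Pac",0.872
"Cu","Molecular sieve",1,"Pac",0.989
"Cu","Halloysite",1,"Pac",0.975
"Cu","Sepiolite",1,"Pac",0.934
"Cu","Expanded clay",1,"Pac",0.934
"Cu","Biochar",1,"Pac",1.068
"Cu","Zeolite",1,"Pac",1.4
"Ni","Control",1,"Pac",1.174
"Ni","Molecular sieve",1,"Pac",1.227
"Ni","Halloysite",1,"Pac",1.356
"Ni","Sepiolite",1,"Pac",1.32
"Ni","Expanded clay",1,"Pac",1.51
"Ni","Biochar",1,"Pac",1.406
"Ni","Zeolite",1,"Pac",1.421
"Zn","Control",1,"Pac",1.236
"Zn","Molecular sieve",1,"Pac",1.563
"Zn","Halloysite",1,"Pac",1.369
"Zn","Sepiolite",1,"Pac",1.679
"Zn","Expanded clay",1,"Pac",1.521
"Zn","Biochar",1,"Pac",1.403
"Zn","Zeolite",1,"Pac",1.428
"C0","Control",1,"Pal",1.349
"C0","Molecular sieve",1,"Pal",1.406
"C0","Halloysite",1,"Pal",1.404
"C0","Sepiolite",1,"Pal",1.544
"C0","Expanded clay",1,"Pal",1.424
"C0","Biochar",1,"Pal",1.574
"C0","Zeolite",1,"Pal",1.578
"Cu","Control",1,"Pal",0.97
"Cu","Molecular sieve",1,"Pal",1.024
"Cu","Halloysite",1,"Pal",1.118
"Cu","Sepiolite",1,"Pal",1.337
"Cu","Expanded clay",1,"Pal",0.988
"Cu","Biochar",1,"Pal",1.008
"Cu","Zeolite",1,"Pal",1.131
"Ni","Control",1,"Pal",1.014
"Ni","Molecular sieve",1,"Pal",1.252
"Ni","Halloysite",1,"Pal",1.032
"Ni","Sepiolite",1,"Pal",1.239
"Ni","Expanded clay",1,"Pal",1.12
"Ni","Biochar",1,"Pal",1.089
"Ni","Zeolite",1,"Pal",1.06
"Zn","Control",1,"Pal",1.152
"Zn","Molecular sieve",1,"Pal",1.344
"Zn","Halloysite",1,"Pal",1.293
"Zn","Sepiolite",1,"Pal",1.239
"Zn","Expanded clay",1,"Pal",1.299
"Zn","Biochar",1,"Pal",1.232
"Zn","Zeolite",1,"Pal",1.225
"C0","Control",1,"Aryl",0.188
"C0","Molecular sieve",1,"Aryl",0.218
"C0","Halloysite",1,"Aryl",0.216
"C0","Sepiolite",1,"Aryl",0.204
"C0","Expanded clay",1,"Aryl",0.2
"C0","Biochar",1,"Aryl",0.202
"C0","Zeolite",1,"Aryl",0.206
"Cu","Control",1,"Aryl",0.174
"Cu","Molecular sieve",1,"Aryl",0.202
"Cu","Halloysite",1,"Aryl",0.206
"Cu","Sepiolite",1,"Aryl",0.196
"Cu","Expanded clay",1,"Aryl",0.196
"Cu","Biochar",1,"Aryl",0.192
"Cu","Zeolite",1,"Aryl",0.196
"Ni","Control",1,"Aryl",0.17
"Ni","Molecular sieve",1,"Aryl",0.214
"Ni","Halloysite",1,"Aryl",0.192
"Ni","Sepiolite",1,"Aryl",0.188
"Ni","Expanded clay",1,"Aryl",0.184
"Ni","Biochar",1,"Aryl",0.18
"Ni","Zeolite",1,"Aryl",0.21
"Zn","Control",1,"Aryl",0.17
"Zn","Molecular sieve",1,"Aryl",0.194
"Zn","Halloysite",1,"Aryl",0.188
"Zn","Sepiolite",1,"Aryl",0.182
"Zn","Expanded clay",1,"Aryl",0.196
"Zn","Biochar",1,"Aryl",0.196
"Zn","Zeolite",1,"Aryl",0.212
"C0","Control",1,"Glu",0.55
"C0","Molecular sieve",1,"Glu",0.661
"C0","Halloysite",1,"Glu",0.761
"C0","Sepiolite",1,"Glu",0.709
"C0","Expanded clay",1,"Glu",0.665
"C0","Biochar",1,"Glu",0.702
"C0","Zeolite",1,"Glu",0.721
"Cu","Control",1,"Glu",0.543
"Cu","Molecular sieve",1,"Glu",0.565
"Cu","Halloysite",1,"Glu",0.592
"Cu","Sepiolite",1,"Glu",0.587
"Cu","Expanded clay",1,"Glu",0.635
"Cu","Biochar",1,"Glu",0.661
"Cu","Zeolite",1,"Glu",0.629
"Ni","Control",1,"Glu",0.523
"Ni","Molecular sieve",1,"Glu",0.661
"Ni","Halloysite",1,"Glu",0.595
"Ni","Sepiolite",1,"Glu",0.693
"Ni","Expanded clay",1,"Glu",0.626
"Ni","Biochar",1,"Glu",0.626
"Ni","Zeolite",1,"Glu",0.701
"Zn","Control",1,"Glu",0.64
"Zn","Molecular sieve",1,"Glu",0.751
"Zn","Halloysite",1,"Glu",0.773
"Zn","Sepiolite",1,"Glu",0.64
"Zn","Expanded clay",1,"Glu",0.739
"Zn","Biochar",1,"Glu",0.713
"Zn","Zeolite",1,"Glu",0.82
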