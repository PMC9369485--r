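"response","unit"
"Org","10^9 cfu/kg d.m."
"Act","10^9 cfu/kg d.m."
"Fun","10^7 cfu/kg d.m."
"Deh","umol TFF/kg d.m./h"
"Cat","mol O2/kg d.m./h"
"Ure","mmol N-NH4/kg d.m./h"
"Pac","mmol PN/kg d.m./h"
"Pal","mmol PN/kg d.m./h"
"Aryl","mmol PN/kg d.m./h"
"Glu","mmol PN/kg d.m./h"
"Shoots","g d.m./pot"
"Roots","g d.m./pot"
"SPAD","SPAD units"
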