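drug,strength_mg,country,coverage_days
pp1m,25,NL,28
pp1m,50,NL,28
pp1m,75,NL,28
pp1m,100,NL,28
pp1m,150,NL,28
pp1m,25,BE,28
pp1m,50,BE,28
pp1m,75,BE,28
pp1m,100,BE,28
pp1m,150,BE,28
risperidone_microspheres,25,NL,14
risperidone_microspheres,37.5,NL,14
risperidone_microspheres,50,NL,14
risperidone_microspheres,25,BE,14
risperidone_microspheres,37.5,BE,14
risperidone_microspheres,50,BE,14
haloperidol_decanoate,50,NL,28
haloperidol_decanoate,100,NL,28
haloperidol_decanoate,150,NL,28
haloperidol_decanoate,50,BE,28
haloperidol_decanoate,100,BE,28
haloperidol_decanoate,150,BE,28
olanzapine_pamoate,210,NL,28
olanzapine_pamoate,300,NL,NA
olanzapine_pamoate,405,NL,14
olanzapine_pamoate,210,BE,28
olanzapine_pamoate,300,BE,NA
olanzapine_pamoate,405,BE,28
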