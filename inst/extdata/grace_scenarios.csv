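scenario,drug,pack_days,grace_days
base,pp1m,NA,28
base,risperidone_microspheres,NA,28
base,haloperidol_decanoate,NA,28
base,olanzapine_pamoate,NA,28
sensitivity,pp1m,NA,60
sensitivity,risperidone_microspheres,NA,60
sensitivity,haloperidol_decanoate,NA,60
sensitivity,olanzapine_pamoate,NA,60
lower,pp1m,NA,7
lower,risperidone_microspheres,NA,3
lower,haloperidol_decanoate,NA,7
lower,olanzapine_pamoate,14,3
lower,olanzapine_pamoate,28,7
upper,pp1m,NA,390
upper,risperidone_microspheres,NA,390
upper,haloperidol_decanoate,NA,390
upper,olanzapine_pamoate,NA,390
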