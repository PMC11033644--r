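term,verb
pain,false
painful,false
pained,false
ache,true
aching muscles,false
sore,false
soreness,false
headache,false
migraine,false
myalgia,false
back pain,false
backache,false
stomach cramps,false
cramp,false
stomach ache,false
chest pain,false
abdominal pain,false
joint pain,false
toothache,false
earache,false
neuralgia,false
sciatica,false
discomfort,false
tenderness,false
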