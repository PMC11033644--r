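term,region,concept_id
foot,lower_limbs,
feet,lower_limbs,
ankle,lower_limbs,
leg,lower_limbs,
knee,lower_limbs,
calf,lower_limbs,
calves,lower_limbs,
thigh,lower_limbs,
toe,lower_limbs,
chest,upper_body_excl_back,
side of chest,upper_body_excl_back,
upper body,upper_body_excl_back,
torso,upper_body_excl_back,
hand,upper_limbs,
wrist,upper_limbs,
arm,upper_limbs,
elbow,upper_limbs,
thumb,upper_limbs,
shoulder,upper_limbs,
stomach,stomach_abdomen,
abdomen,stomach_abdomen,
groin,stomach_abdomen,
bladder,stomach_abdomen,
prostate,stomach_abdomen,
head,head_neck,
tooth,head_neck,
teeth,head_neck,
face,head_neck,
mouth,head_neck,
tongue,head_neck,
eye,head_neck,
ear,head_neck,
neck,head_neck,
entire body,non_specific,
skin,non_specific,
muscle,non_specific,
joint,non_specific,
back,back,
lower back,back,
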