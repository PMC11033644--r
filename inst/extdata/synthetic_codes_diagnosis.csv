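code,kind,description
N131.,diagnosis,back pain (synthetic fixture code)
N142.,diagnosis,neck pain (synthetic fixture code)
N245.,diagnosis,shoulder pain (synthetic fixture code)
N094.,diagnosis,joint pain (synthetic fixture code)
F261.,diagnosis,trigeminal neuralgia (synthetic fixture code)
R065.,diagnosis,referred ear pain (synthetic fixture code)
N05..,diagnosis,osteoarthritis (synthetic fixture code)
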