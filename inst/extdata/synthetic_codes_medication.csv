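code,kind,description
dn21.,medication,paracetamol 500mg tablets (synthetic fixture code)
dn22.,medication,ibuprofen 400mg tablets (synthetic fixture code)
dn31.,medication,codeine phosphate 30mg tablets (synthetic fixture code)
dn41.,medication,tramadol 50mg capsules (synthetic fixture code)
dn51.,medication,naproxen 250mg tablets (synthetic fixture code)
dnA1.,medication,amitriptyline 10mg for neuropathic pain (synthetic fixture code)
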