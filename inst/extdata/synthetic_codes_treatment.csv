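code,kind,description
8HTp.,treatment,referral to pain clinic (synthetic fixture code)
9N1p.,treatment,seen in pain clinic (synthetic fixture code)
8Hkp.,treatment,under care of pain management specialist (synthetic fixture code)
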