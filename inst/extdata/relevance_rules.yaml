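# Default rule set for relevance classification of pain-keyword hits.
# Rule families apply in fixed precedence:
#   form > misspelling > negation > hypothetical > metaphorical > affirmed.
# Cue lists are matched lowercase; scope is in tokens before the keyword hit.
negation:
  scope: 5
  cues:
    - "no"
    - "not"
    - "denies"
    - "denied"
    - "denying"
    - "without"
    - "nil"
    - "never"
    - "free of"
    - "absence of"
    - "no complaint of"
    - "no evidence of"
hypothetical:
  scope: 10
  cues:
    - "risk of"
    - "fear that"
    - "fear of"
    - "in case of"
    - "may cause"
    - "might cause"
    - "would cause"
    - "will cause"
    - "could cause"
    - "to avoid"
    - "to prevent"
    - "worried that"
form_patterns:
  - "for example,"
  - "\\be\\.g\\."
  - "yes\\s*/\\s*no"
  - "y/n"
  - "please (circle|rate|tick)"
  - "tick all that apply"
  - "\\[\\s*\\]"
misspelling_patterns:
  - "\\bpained\\b and (decorat|paint|plaster|wallpaper|sand|tile|varnish)"
metaphorical_patterns:
  - "painful (feeling|memor|consequence|thought|emotion|reminder|divorce|breakup|separation)"
  - "too painful to"
  - "pain will end when"
  - "emotional(ly)? pain"
  - "pain of (losing|loss|grief)"
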