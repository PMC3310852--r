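# Editable cue lexicon for rule-based relationship suggestion.
# Patterns are case-insensitive regular expressions matched against the
# child concept's preferred title. When several fire, precedence is
# SubProcess > Agent > Patient > Instrument > Complexity.
relation	pattern
SubProcess	\bstarting\b
SubProcess	\bsustaining\b
SubProcess	\bending\b
SubProcess	\bcompleting\b
SubProcess	\bpreparing\b
SubProcess	\bterminating\b
Agent	with one person
Agent	with many people
Agent	\balone\b
Agent	in a group
Agent	with others
Patient	\bobjects?\b
Patient	\bmessages\b
Instrument	\busing\b
Instrument	\bby means of\b
Instrument	\bdevices?\b
Complexity	\bsimple\b
Complexity	\bcomplex\b
Complexity	\bsingle\b
Complexity	\bmultiple\b
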