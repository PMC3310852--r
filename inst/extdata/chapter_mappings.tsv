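# Chapter-level mappings from the ICF Activities and Participation
# component to SUMO: exactly the chapters for which a chapter-wide SUMO
# superclass is stated in the published analysis. Chapters d1, d3, d7, d8
# and d9 have no chapter-wide mapping (only block/category-level links or
# none at all) and so do not appear here.
source_code	target_concept	match_kind	note
d2	IntentionalProcess	broader	generic classification of tasks; no more specific mapping
d4	Motion	broader	Motion in SUMO is not an IntentionalProcess
d5	IntentionalProcess	broader
d6	IntentionalProcess	broader
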