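{"id": "snippet1", "text": "One construct commonly used to stratify samples is age of language acquisition, based on age of first words or phrases. Delayed language is defined on the ADI-R by age of first words >= 24 and age of first phrases >= 33-36 months."}
{"id": "snippet2", "text": "Language Acquisition Groups defined based on ADI-R items 9 (Age of First Words) and 10 (Age of First Phrases). Individuals were grouped as follows: NDW (not delayed words): acquired words <= 24 months. DW (delayed words): acquired words > 24 months. NW (no words): no words at time of ADI-R. NDP (not delayed phrases): acquired phrases <= 33 months. DP (delayed phrases): acquired phrases > 33 months. NP (no phrases): no phrases at time of ADI-R."}
{"id": "background1", "text": "Social interaction impairments were assessed with a calibrated severity score at enrollment, and children scoring above the clinical threshold were classified as severely affected on that domain."}
{"id": "background2", "text": "Participants completed standardized diagnostic instruments and demographic questionnaires. Inclusion required a confirmed community diagnosis and parental consent before any study procedures."}
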