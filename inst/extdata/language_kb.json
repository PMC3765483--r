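{
  "concepts": [
    {"id": "autism_phenotype_level", "label": "Autism Phenotype Level", "parents": []},
    {"id": "language_acquisition", "label": "Language Acquisition", "parents": ["autism_phenotype_level"]},
    {"id": "status_age_words", "label": "Status of Age of Words", "parents": ["language_acquisition"]},
    {"id": "status_age_phrases", "label": "Status of Age of Phrases", "parents": ["language_acquisition"]},
    {"id": "delayed_words", "label": "Delayed Words", "parents": ["status_age_words"]},
    {"id": "words_not_delayed", "label": "Words Not Delayed", "parents": ["status_age_words"]},
    {"id": "no_words", "label": "No Words", "parents": ["status_age_words"]},
    {"id": "delayed_phrases", "label": "Delayed Phrases", "parents": ["status_age_phrases"]},
    {"id": "phrases_not_delayed", "label": "Phrases Not Delayed", "parents": ["status_age_phrases"]},
    {"id": "no_phrases", "label": "No Phrases", "parents": ["status_age_phrases"]},
    {"id": "adi_r", "label": "ADI-R", "parents": []}
  ],
  "properties": [
    {"id": "adi-r2003:ADI_2003_acqorlossoflang_aword", "label": "Age of First Words", "kind": "data_property"},
    {"id": "adi-r2003:ADI_2003_acqorlossoflang_aphrase", "label": "Age of First Phrases", "kind": "data_property"},
    {"id": "adi-r2003:SubjectKey", "label": "Subject Key", "kind": "data_property"},
    {"id": "autism-core:subject_has_quality_or_disposition", "label": "subject has quality or disposition", "kind": "object_property"}
  ],
  "rules": [
    {
      "id": "delayed_words_rule",
      "defines": "delayed_words",
      "body": [
        {"pred": "adi_r", "kind": "class", "args": ["?a"]},
        {"pred": "adi-r2003:ADI_2003_acqorlossoflang_aword", "kind": "data_property", "args": ["?a", "?wordage"]},
        {"pred": "swrlb:greaterThan", "kind": "builtin", "args": ["?wordage", "24"]},
        {"pred": "adi-r2003:SubjectKey", "kind": "data_property", "args": ["?a", "?subjectID"]},
        {"pred": "swrlx:createOWLThing", "kind": "builtin", "args": ["?phenotype", "?subjectID"]}
      ],
      "head": [
        {"pred": "delayed_words", "kind": "class", "args": ["?phenotype"]},
        {"pred": "autism-core:subject_has_quality_or_disposition", "kind": "object_property", "args": ["?subjectID", "?phenotype"]}
      ]
    },
    {
      "id": "delayed_phrases_rule",
      "defines": "delayed_phrases",
      "body": [
        {"pred": "adi_r", "kind": "class", "args": ["?a"]},
        {"pred": "adi-r2003:ADI_2003_acqorlossoflang_aphrase", "kind": "data_property", "args": ["?a", "?phraseage"]},
        {"pred": "swrlb:greaterThan", "kind": "builtin", "args": ["?phraseage", "33"]},
        {"pred": "adi-r2003:SubjectKey", "kind": "data_property", "args": ["?a", "?subjectID"]},
        {"pred": "swrlx:createOWLThing", "kind": "builtin", "args": ["?phenotype", "?subjectID"]}
      ],
      "head": [
        {"pred": "delayed_phrases", "kind": "class", "args": ["?phenotype"]},
        {"pred": "autism-core:subject_has_quality_or_disposition", "kind": "object_property", "args": ["?subjectID", "?phenotype"]}
      ]
    }
  ]
}
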