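{
  "schema_version": "1.0",
  "name": "LPFS-qIAT",
  "target_labels": ["Impaired", "Not impaired"],
  "logical_labels": ["True", "False"],
  "positive_pole": "Impaired",
  "statements": [
    {"item_id": "imp01", "text": "I often do not know who I really am", "category": "Impaired", "mirror_of": "not01"},
    {"item_id": "imp02", "text": "I often think very negatively about myself", "category": "Impaired", "mirror_of": "not02"},
    {"item_id": "imp03", "text": "My emotions change without me having a grip on them", "category": "Impaired", "mirror_of": "not03"},
    {"item_id": "imp04", "text": "I have no sense of where I want to go in my life", "category": "Impaired", "mirror_of": "not04"},
    {"item_id": "imp05", "text": "I often do not understand my own thoughts and feelings", "category": "Impaired", "mirror_of": "not05"},
    {"item_id": "imp06", "text": "I often make unrealistic demands of myself", "category": "Impaired", "mirror_of": "not06"},
    {"item_id": "imp07", "text": "I often have difficulty understanding the thoughts and feelings of others", "category": "Impaired", "mirror_of": "not07"},
    {"item_id": "imp08", "text": "I can't stand it when others have a different opinion than me", "category": "Impaired", "mirror_of": "not08"},
    {"item_id": "imp09", "text": "I often don't understand the effect my behavior has on others", "category": "Impaired", "mirror_of": "not09"},
    {"item_id": "imp10", "text": "My relationships and friendships usually don't last long", "category": "Impaired", "mirror_of": "not10"},
    {"item_id": "imp11", "text": "I often feel uncomfortable when relationships become more intimate", "category": "Impaired", "mirror_of": "not11"},
    {"item_id": "imp12", "text": "I often have trouble cooperating with others", "category": "Impaired", "mirror_of": "not12"},
    {"item_id": "not01", "text": "I generally know who I really am", "category": "Not impaired", "mirror_of": "imp01"},
    {"item_id": "not02", "text": "I rarely think very negatively about myself", "category": "Not impaired", "mirror_of": "imp02"},
    {"item_id": "not03", "text": "My emotions are usually well regulated and stable", "category": "Not impaired", "mirror_of": "imp03"},
    {"item_id": "not04", "text": "I have a good sense of where I want to go in my life", "category": "Not impaired", "mirror_of": "imp04"},
    {"item_id": "not05", "text": "I often understand my own thoughts and feelings", "category": "Not impaired", "mirror_of": "imp05"},
    {"item_id": "not06", "text": "I often make realistic demands of myself", "category": "Not impaired", "mirror_of": "imp06"},
    {"item_id": "not07", "text": "I often understand the thoughts and feelings of others", "category": "Not impaired", "mirror_of": "imp07"},
    {"item_id": "not08", "text": "I can appreciate others' opinions, even when we disagree", "category": "Not impaired", "mirror_of": "imp08"},
    {"item_id": "not09", "text": "I often understand the effect my behavior has on others", "category": "Not impaired", "mirror_of": "imp09"},
    {"item_id": "not10", "text": "My relationships and friendships usually last long", "category": "Not impaired", "mirror_of": "imp10"},
    {"item_id": "not11", "text": "I often feel comfortable when relationships become more intimate", "category": "Not impaired", "mirror_of": "imp11"},
    {"item_id": "not12", "text": "I often cooperate with others well", "category": "Not impaired", "mirror_of": "imp12"},
    {"item_id": "tru01", "text": "I am looking at a computer screen", "category": "True", "mirror_of": null},
    {"item_id": "tru02", "text": "I am participating in an experiment on the internet", "category": "True", "mirror_of": null},
    {"item_id": "tru03", "text": "I am doing a psychology experiment", "category": "True", "mirror_of": null},
    {"item_id": "tru04", "text": "I am putting my fingers on the keyboard", "category": "True", "mirror_of": null},
    {"item_id": "tru05", "text": "I am in front of the computer", "category": "True", "mirror_of": null},
    {"item_id": "fal01", "text": "I am sunbathing at the beach", "category": "False", "mirror_of": null},
    {"item_id": "fal02", "text": "I am climbing a steep mountain", "category": "False", "mirror_of": null},
    {"item_id": "fal03", "text": "I am currently playing an electric guitar", "category": "False", "mirror_of": null},
    {"item_id": "fal04", "text": "I am buying groceries in the local grocery store", "category": "False", "mirror_of": null},
    {"item_id": "fal05", "text": "I am playing football on the grass", "category": "False", "mirror_of": null}
  ],
  "blocks": [
    {"index": 1, "role": "learning", "task": "target-only", "n_trials": 40,
     "left_labels": ["Impaired"], "right_labels": ["Not impaired"]},
    {"index": 2, "role": "learning", "task": "logical-only", "n_trials": 20,
     "left_labels": ["True"], "right_labels": ["False"]},
    {"index": 3, "role": "practice", "task": "combined", "n_trials": 20,
     "left_labels": ["Impaired", "True"], "right_labels": ["Not impaired", "False"]},
    {"index": 4, "role": "test", "task": "combined", "n_trials": 40,
     "left_labels": ["Impaired", "True"], "right_labels": ["Not impaired", "False"]},
    {"index": 5, "role": "practice", "task": "target-only-reversed", "n_trials": 40,
     "left_labels": ["Not impaired"], "right_labels": ["Impaired"]},
    {"index": 6, "role": "practice", "task": "combined-reversed", "n_trials": 20,
     "left_labels": ["Not impaired", "True"], "right_labels": ["Impaired", "False"]},
    {"index": 7, "role": "test", "task": "combined-reversed", "n_trials": 40,
     "left_labels": ["Not impaired", "True"], "right_labels": ["Impaired", "False"]}
  ]
}
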