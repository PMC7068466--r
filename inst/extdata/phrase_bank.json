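{
  "direct_phrases": [
    "acute low back pain",
    "acute lbp",
    "acute low bp",
    "acute back pain"
  ],
  "paraphrases": [
    "shooting pain down into the lower extremities",
    "limited spine range of motion",
    "vertebral tenderness on palpation",
    "diffuse pain in lumbar muscles",
    "sudden onset lower back injury after lifting",
    "severe lumbar muscle spasm since yesterday",
    "paraspinal tenderness with decreased lumbar flexion",
    "pain radiating down the left leg with positive straight leg raise"
  ],
  "support_phrases": [
    "prescribed muscle relaxant",
    "prescribed flexeril for the spasm",
    "started cyclobenzaprine ten milligrams",
    "naproxen for acute low back discomfort",
    "recommended rtw full duty quick",
    "back brace for back pain recommended",
    "obtain lumbar spine mri if not improving",
    "recommendation rtw visit in two weeks",
    "advised heat and ice with early mobilization"
  ],
  "signal_templates": [
    "patient presents today with {X}",
    "chief complaint is {X}",
    "assessment {X} following recent strain",
    "patient reports {X} since this morning",
    "impression {X}"
  ],
  "negation_templates": [
    "denies {X}",
    "no evidence of {X}",
    "no {X} reported today",
    "patient without {X}",
    "{X} ruled out on exam"
  ],
  "background_sentences": [
    "patient seen today for routine follow up visit",
    "blood pressure well controlled on current regimen",
    "type two diabetes mellitus stable on metformin",
    "continues lisinopril ten milligrams daily",
    "annual influenza vaccination administered today",
    "reviewed medication list and updated allergies",
    "denies chest discomfort or palpitations",
    "lungs clear to auscultation bilaterally",
    "heart regular rate and rhythm without murmur",
    "abdomen soft nontender with normal bowel sounds",
    "right knee discomfort improved with physical therapy",
    "left shoulder range of motion intact",
    "mild seasonal allergies managed with loratadine",
    "screening colonoscopy discussed and ordered",
    "lipid panel reviewed and statin continued",
    "patient ambulates with steady gait today",
    "no peripheral edema noted on examination",
    "asthma well controlled with rescue inhaler rarely used",
    "tobacco cessation counseling provided again",
    "alcohol use is social and infrequent",
    "sleep quality reported as adequate most nights",
    "diet and exercise counseling reviewed in detail",
    "weight stable compared with prior visit",
    "depression screening negative at this visit",
    "thyroid function tests within normal limits",
    "follow up labs ordered for next month",
    "skin examination without suspicious lesions",
    "bilateral hearing grossly intact",
    "vision corrected with current prescription lenses",
    "immunizations are up to date per registry",
    "hypertension follow up scheduled in three months",
    "gastroesophageal reflux controlled with omeprazole",
    "migraine frequency reduced on current prophylaxis",
    "urinalysis unremarkable at todays visit",
    "vitamin d supplementation continued",
    "plantar fasciitis improving with stretching exercises",
    "carpal tunnel symptoms stable with night splints",
    "neck stiffness resolved since last appointment",
    "patient works at a desk most of the day",
    "encouraged daily walking and stretching program",
    "referred to nutrition services for weight management",
    "cervical cancer screening current per guidelines",
    "prostate screening discussed risks and benefits",
    "renal function stable on repeat chemistries",
    "anemia workup unremarkable this year",
    "patient verbalized understanding of the plan",
    "return precautions discussed with patient",
    "will continue current home exercise program",
    "medication refills sent to preferred pharmacy",
    "care coordination note shared with specialist"
  ]
}
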