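{
  "_comment": "Coding dictionary for the nine nodule characteristics. Private codes use the nonstandard scheme 99LIDCQIICR ('99' flags a nonstandard scheme). The code VALUES here are this package's own synthetic assignments; the meanings follow the documented LIDC rating scales.",
  "scheme": "99LIDCQIICR",
  "attributes": {
    "subtlety": {
      "concept": {"value": "301", "scheme": "99LIDCQIICR", "meaning": "Subtlety score"},
      "values": [
        {"rating": 1, "value": "3011", "meaning": "1 out of 5 (Extremely Subtle)"},
        {"rating": 2, "value": "3012", "meaning": "2 out of 5 (Moderately Subtle)"},
        {"rating": 3, "value": "3013", "meaning": "3 out of 5 (Fairly Subtle)"},
        {"rating": 4, "value": "3014", "meaning": "4 out of 5 (Moderately Obvious)"},
        {"rating": 5, "value": "3015", "meaning": "5 out of 5 (Obvious)"}
      ]
    },
    "internalStructure": {
      "concept": {"value": "302", "scheme": "99LIDCQIICR", "meaning": "Internal structure"},
      "values": [
        {"rating": 1, "value": "3021", "meaning": "Soft Tissue"},
        {"rating": 2, "value": "3022", "meaning": "Fluid"},
        {"rating": 3, "value": "3023", "meaning": "Fat"},
        {"rating": 4, "value": "3024", "meaning": "Air"}
      ]
    },
    "calcification": {
      "concept": {"value": "303", "scheme": "99LIDCQIICR", "meaning": "Calcification"},
      "values": [
        {"rating": 1, "value": "3031", "meaning": "Popcorn calcification"},
        {"rating": 2, "value": "3032", "meaning": "Laminated calcification"},
        {"rating": 3, "value": "3033", "meaning": "Solid calcification"},
        {"rating": 4, "value": "3034", "meaning": "Non-central calcification"},
        {"rating": 5, "value": "3035", "meaning": "Central calcification"},
        {"rating": 6, "value": "3036", "meaning": "Absent"}
      ]
    },
    "sphericity": {
      "concept": {"value": "304", "scheme": "99LIDCQIICR", "meaning": "Sphericity"},
      "values": [
        {"rating": 1, "value": "3041", "meaning": "1 out of 5 (Linear)"},
        {"rating": 2, "value": "3042", "meaning": "2 out of 5 (Ovoid/Linear)"},
        {"rating": 3, "value": "3043", "meaning": "3 out of 5 (Ovoid)"},
        {"rating": 4, "value": "3044", "meaning": "4 out of 5 (Ovoid/Round)"},
        {"rating": 5, "value": "3045", "meaning": "5 out of 5 (Round)"}
      ]
    },
    "margin": {
      "concept": {"value": "305", "scheme": "99LIDCQIICR", "meaning": "Margin"},
      "values": [
        {"rating": 1, "value": "3051", "meaning": "1 out of 5 (Poorly Defined)"},
        {"rating": 2, "value": "3052", "meaning": "2 out of 5 (Near Poorly Defined)"},
        {"rating": 3, "value": "3053", "meaning": "3 out of 5 (Medium Margin)"},
        {"rating": 4, "value": "3054", "meaning": "4 out of 5 (Near Sharp)"},
        {"rating": 5, "value": "3055", "meaning": "5 out of 5 (Sharp)"}
      ]
    },
    "lobulation": {
      "concept": {"value": "306", "scheme": "99LIDCQIICR", "meaning": "Lobulation"},
      "values": [
        {"rating": 1, "value": "3061", "meaning": "1 out of 5 (No Lobulation)"},
        {"rating": 2, "value": "3062", "meaning": "2 out of 5 (Nearly No Lobulation)"},
        {"rating": 3, "value": "3063", "meaning": "3 out of 5 (Medium Lobulation)"},
        {"rating": 4, "value": "3064", "meaning": "4 out of 5 (Near Marked Lobulation)"},
        {"rating": 5, "value": "3065", "meaning": "5 out of 5 (Marked Lobulation)"}
      ]
    },
    "spiculation": {
      "concept": {"value": "307", "scheme": "99LIDCQIICR", "meaning": "Spiculation"},
      "values": [
        {"rating": 1, "value": "3071", "meaning": "1 out of 5 (No Spiculation)"},
        {"rating": 2, "value": "3072", "meaning": "2 out of 5 (Nearly No Spiculation)"},
        {"rating": 3, "value": "3073", "meaning": "3 out of 5 (Medium Spiculation)"},
        {"rating": 4, "value": "3074", "meaning": "4 out of 5 (Near Marked Spiculation)"},
        {"rating": 5, "value": "3075", "meaning": "5 out of 5 (Marked Spiculation)"}
      ]
    },
    "texture": {
      "concept": {"value": "308", "scheme": "99LIDCQIICR", "meaning": "Texture"},
      "values": [
        {"rating": 1, "value": "3081", "meaning": "1 out of 5 (Non-Solid/GGO)"},
        {"rating": 2, "value": "3082", "meaning": "2 out of 5 (Non-Solid/Mixed)"},
        {"rating": 3, "value": "3083", "meaning": "3 out of 5 (Part Solid/Mixed)"},
        {"rating": 4, "value": "3084", "meaning": "4 out of 5 (Solid/Mixed)"},
        {"rating": 5, "value": "3085", "meaning": "5 out of 5 (Solid)"}
      ]
    },
    "malignancy": {
      "concept": {"value": "309", "scheme": "99LIDCQIICR", "meaning": "Malignancy"},
      "values": [
        {"rating": 1, "value": "3091", "meaning": "1 out of 5 (Highly Unlikely)"},
        {"rating": 2, "value": "3092", "meaning": "2 out of 5 (Moderately Unlikely)"},
        {"rating": 3, "value": "3093", "meaning": "3 out of 5 (Indeterminate Likelihood)"},
        {"rating": 4, "value": "3094", "meaning": "4 out of 5 (Moderately Suspicious)"},
        {"rating": 5, "value": "3095", "meaning": "5 out of 5 (Highly Suspicious)"}
      ]
    }
  }
}
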