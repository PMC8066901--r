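{
  "sheet_id": "refined",
  "critical_limit": 4,
  "parameters": [
    {
      "name": "Body condition",
      "category": "general_appearance",
      "levels": {
        "0": "Good",
        "1": "Altered body condition",
        "2": "Emaciated"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Body weight",
      "category": "general_appearance",
      "levels": {
        "0": "Normal",
        "1": "Loss of <10%",
        "2": "Loss of 10-20%",
        "3": "Loss of >20% (euthanasia)"
      },
      "euthanasia_scores": 3
    },
    {
      "name": "Posture",
      "category": "general_appearance",
      "levels": {
        "0": "Normal posture",
        "1": "Posture changes (orthopnea posture)"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Hair appearance and grooming",
      "category": "general_appearance",
      "levels": {
        "0": "Normal",
        "1": "Lack of grooming",
        "2": "Bad-looking hair and chromodachryorrhea",
        "3": "Chromodachryorrhea and hair with a very bad appearance"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Mucous color",
      "category": "general_appearance",
      "levels": {
        "0": "Normal",
        "1": "Slightly anemic",
        "2": "Moderately anemic",
        "3": "Severe anemia"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Eyes, ears, and whiskers",
      "category": "general_appearance",
      "levels": {
        "0": "Normal",
        "1": "Partially closed eyes, droopy ears, and forward whiskers",
        "2": "Completely closed eyes, droopy and curved ears, and forward and bunched whiskers"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Mental status",
      "category": "general_appearance",
      "levels": {
        "0": "Normal",
        "1": "Lethargic",
        "3": "Stupor/coma (euthanasia)"
      },
      "euthanasia_scores": 3
    },
    {
      "name": "Response to external stimuli",
      "category": "behavior",
      "levels": {
        "0": "Normal",
        "1": "Moderate response",
        "2": "Moderate response with vocalization",
        "3": "Violent response"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Hydration status",
      "category": "clinical_signs",
      "levels": {
        "0": "Normal",
        "1": "Abnormal skin pinch test (>2 s)"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Stool appearance",
      "category": "clinical_signs",
      "levels": {
        "0": "Normal",
        "1": "Diarrhea",
        "2": "Black (digested blood)",
        "3": "Bloody stool"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Convulsions",
      "category": "clinical_signs",
      "levels": {
        "0": "Absence",
        "3": "Presence"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Dimension of damage caused by injections",
      "category": "clinical_signs",
      "levels": {
        "0": "Without skin lesion",
        "1": "Lesion with diameter <=8 mm",
        "2": "Lesion with diameters of >=9 and <=14 mm",
        "3": "Lesion with diameters of >=15 mm"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Macroscopic appearance of induced skin lesions",
      "category": "clinical_signs",
      "levels": {
        "0": "Absence of necrosis",
        "3": "Presence of necrosis (euthanasia)"
      },
      "euthanasia_scores": 3
    },
    {
      "name": "Infection of induced skin lesions",
      "category": "clinical_signs",
      "levels": {
        "0": "Absence of infection",
        "3": "Presence of inflammatory exudate (euthanasia)"
      },
      "euthanasia_scores": 3
    },
    {
      "name": "Abdominal temperature elevation",
      "category": "clinical_signs",
      "levels": {
        "0": "Within 1 SD of concurrent control mean",
        "1": "1-2 SD above concurrent control mean",
        "2": ">2 SD above concurrent control mean"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Priapism",
      "category": "clinical_signs",
      "levels": {
        "0": "Absent",
        "2": "Present"
      },
      "euthanasia_scores": []
    },
    {
      "name": "Sudden body weight gain",
      "category": "clinical_signs",
      "levels": {
        "0": "Weekly ponderal gain <6%",
        "1": "Weekly ponderal gain 6-10%",
        "2": "Weekly ponderal gain >10%"
      },
      "euthanasia_scores": []
    }
  ]
}
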