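# Pattern Element Scale (PES): 11 pattern-element subscales, 7 weighted
# clinical-feature items each. A subscale total of `cutoff` points or more
# diagnoses that pattern element.
cutoff: 6
subscales:
  - id: kidney_deficiency
    label: "Kidney deficiency"
    items:
      - {id: kidney_deficiency_1, label: "Limp and aching lumbar", weight: 5}
      - {id: kidney_deficiency_2, label: "Urinary incontinence", weight: 5}
      - {id: kidney_deficiency_3, label: "Deafness", weight: 4}
      - {id: kidney_deficiency_4, label: "Sexual hypoactivity", weight: 4}
      - {id: kidney_deficiency_5, label: "Frequent micturition with clear urine", weight: 3}
      - {id: kidney_deficiency_6, label: "Dizziness and tinnitus", weight: 2}
      - {id: kidney_deficiency_7, label: "Thready and weak pulse", weight: 1}
  - id: spleen_deficiency
    label: "Spleen deficiency"
    items:
      - {id: spleen_deficiency_1, label: "Decrease of diet and anorexia/reduced appetite", weight: 4.5}
      - {id: spleen_deficiency_2, label: "Involuntary drooling", weight: 4}
      - {id: spleen_deficiency_3, label: "Sloppy stool", weight: 3.5}
      - {id: spleen_deficiency_4, label: "Weakness of four extremities", weight: 3}
      - {id: spleen_deficiency_5, label: "Decrease of diet and abdominal distension", weight: 3}
      - {id: spleen_deficiency_6, label: "Pale tongue with indentation on margin", weight: 3}
      - {id: spleen_deficiency_7, label: "Slow pulse", weight: 2}
  - id: qi_deficiency
    label: "Qi deficiency"
    items:
      - {id: qi_deficiency_1, label: "Shortage of breath and disinclination of talking", weight: 5}
      - {id: qi_deficiency_2, label: "Spontaneous perspiration", weight: 5}
      - {id: qi_deficiency_3, label: "Palpitation", weight: 4}
      - {id: qi_deficiency_4, label: "Hypodynamia", weight: 3}
      - {id: qi_deficiency_5, label: "White and lusterless complexion", weight: 3}
      - {id: qi_deficiency_6, label: "Hyperarousal and timidity", weight: 2}
      - {id: qi_deficiency_7, label: "Thready pulse", weight: 2}
  - id: blood_deficiency
    label: "Blood deficiency"
    items:
      - {id: blood_deficiency_1, label: "Sallow complexion", weight: 5}
      - {id: blood_deficiency_2, label: "Pale tongue and lip", weight: 4}
      - {id: blood_deficiency_3, label: "Dizziness", weight: 3.5}
      - {id: blood_deficiency_4, label: "Palpitation", weight: 3}
      - {id: blood_deficiency_5, label: "Ennui and hypodynamia", weight: 2}
      - {id: blood_deficiency_6, label: "Numbness of extremities", weight: 2}
      - {id: blood_deficiency_7, label: "Thready pulse", weight: 2}
  - id: yin_deficiency
    label: "Yin deficiency"
    items:
      - {id: yin_deficiency_1, label: "Red and dry tongue", weight: 5}
      - {id: yin_deficiency_2, label: "Thin tongue fur", weight: 4.5}
      - {id: yin_deficiency_3, label: "Dry eyes", weight: 4.5}
      - {id: yin_deficiency_4, label: "Emaciation", weight: 4.5}
      - {id: yin_deficiency_5, label: "Thready and rapid pulse", weight: 3}
      - {id: yin_deficiency_6, label: "Dry stool", weight: 3}
      - {id: yin_deficiency_7, label: "Night sweat", weight: 3}
  - id: yang_deficiency
    label: "Yang deficiency"
    items:
      - {id: yang_deficiency_1, label: "Chilly", weight: 5}
      - {id: yang_deficiency_2, label: "Cold limbs", weight: 4}
      - {id: yang_deficiency_3, label: "Diarrhea almost every morning around three to five o'clock", weight: 4.5}
      - {id: yang_deficiency_4, label: "Difficulty in micturition", weight: 3.5}
      - {id: yang_deficiency_5, label: "Blue and purple lip or nail", weight: 3}
      - {id: yang_deficiency_6, label: "Pale tongue with watery tongue fur", weight: 3}
      - {id: yang_deficiency_7, label: "Weak and sunken pulse", weight: 2}
  - id: marrow_deficiency
    label: "Marrow deficiency"
    items:
      - {id: marrow_deficiency_1, label: "Dysbasia", weight: 5.5}
      - {id: marrow_deficiency_2, label: "Drumble/bradyphagia", weight: 5}
      - {id: marrow_deficiency_3, label: "Aching limbs and tibia", weight: 5}
      - {id: marrow_deficiency_4, label: "Loss of tooth/teeth", weight: 4.5}
      - {id: marrow_deficiency_5, label: "Thin pale tongue", weight: 3.5}
      - {id: marrow_deficiency_6, label: "Dry and withered hair", weight: 3.5}
      - {id: marrow_deficiency_7, label: "Somnolence", weight: 2}
  - id: yang_hyperactivity
    label: "Yang hyperactivity"
    items:
      - {id: yang_hyperactivity_1, label: "Irritable mood and irascibility", weight: 5.5}
      - {id: yang_hyperactivity_2, label: "Dizziness and vertigo", weight: 5}
      - {id: yang_hyperactivity_3, label: "Tremoring tongue", weight: 4.5}
      - {id: yang_hyperactivity_4, label: "Subsultus tendinum or jumping of muscle", weight: 4}
      - {id: yang_hyperactivity_5, label: "Tinnitus with a loud wavelike sound", weight: 4}
      - {id: yang_hyperactivity_6, label: "Headache", weight: 4}
      - {id: yang_hyperactivity_7, label: "Wiry pulse/stringy pulse", weight: 3}
  - id: endogenous_heat
    label: "Endogenous heat"
    items:
      - {id: endogenous_heat_1, label: "Halitosis", weight: 5}
      - {id: endogenous_heat_2, label: "Yellow tongue fur", weight: 5}
      - {id: endogenous_heat_3, label: "Red complexion", weight: 4}
      - {id: endogenous_heat_4, label: "Red tongue", weight: 4}
      - {id: endogenous_heat_5, label: "Constipation with dry stool", weight: 2.5}
      - {id: endogenous_heat_6, label: "Bitter taste in mouth", weight: 2}
      - {id: endogenous_heat_7, label: "Rapid pulse", weight: 2}
  - id: phlegm_muddiness
    label: "Phlegm muddiness"
    items:
      - {id: phlegm_muddiness_1, label: "Excessive phlegm", weight: 5}
      - {id: phlegm_muddiness_2, label: "Greasy and turbid tongue fur", weight: 3}
      - {id: phlegm_muddiness_3, label: "Enlarged tongue", weight: 2.5}
      - {id: phlegm_muddiness_4, label: "Nausea", weight: 3}
      - {id: phlegm_muddiness_5, label: "Distension and fullness in chest and stomach", weight: 3}
      - {id: phlegm_muddiness_6, label: "Slippery pulse", weight: 3}
      - {id: phlegm_muddiness_7, label: "Dizziness and demented/madness", weight: 2}
  - id: blood_stasis
    label: "Blood stasis"
    items:
      - {id: blood_stasis_1, label: "Petechia in tongue", weight: 6}
      - {id: blood_stasis_2, label: "Dark purple tongue", weight: 5}
      - {id: blood_stasis_3, label: "Absurd and bizarre thoughts", weight: 4}
      - {id: blood_stasis_4, label: "Dark purple lip", weight: 3.5}
      - {id: blood_stasis_5, label: "Grayish complexion", weight: 3.5}
      - {id: blood_stasis_6, label: "Stabbing pain or oppressive pain", weight: 3}
      - {id: blood_stasis_7, label: "Rough pulse", weight: 2}
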