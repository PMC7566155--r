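{
  "n": 116,
  "description": "Marginal specification transcribing the published cohort summary of 116 deceased cancer patients: exact categorical counts per characteristic, exact means and ranges for day-count columns. Cross-column joints are NOT specified. The primary tumour site rows sum to 115 in the published table; the remaining record is generated as missing.",
  "columns": [
    {"name": "assessment_to_death_days", "type": "integer",
     "mean": 38, "min": 3, "max": 89, "attain_extremes": true},
    {"name": "gender", "type": "categorical",
     "counts": {"male": 52, "female": 64}},
    {"name": "age_group", "type": "categorical",
     "counts": {"20-40": 1, "41-65": 33, "66-80": 58, ">80": 24}},
    {"name": "primary_tumour_site", "type": "categorical",
     "counts": {"gastrointestinal": 40, "lung": 12, "breast": 15, "other": 48},
     "missing_count": 1},
    {"name": "diagnosis_to_death_days", "type": "integer",
     "mean": 922, "min": 2, "max": 10465, "attain_extremes": true},
    {"name": "place_of_death", "type": "categorical",
     "counts": {"home": 21, "hospital": 90, "nursing_home": 5}},
    {"name": "last_chemo_to_death_days", "type": "integer",
     "mean": 34, "min": 0, "max": 247, "attain_extremes": true},
    {"name": "distance_to_centre_km", "type": "integer",
     "mean": 4, "min": 1, "max": 74, "attain_extremes": true},
    {"name": "area_of_residence", "type": "categorical",
     "counts": {"rural": 31, "urban": 85}},
    {"name": "living_arrangements", "type": "categorical",
     "counts": {"alone": 40, "with_spouse": 65, "with_siblings": 2,
                "with_children": 6, "other": 3}},
    {"name": "palliative_physician_visits", "type": "categorical",
     "counts": {"yes": 35, "no": 81}},
    {"name": "palliative_nurse_visits", "type": "categorical",
     "counts": {"yes": 93, "no": 23}},
    {"name": "social_worker", "type": "categorical",
     "counts": {"involved": 49, "not_involved": 67}},
    {"name": "volunteers", "type": "categorical",
     "counts": {"involved": 71, "not_involved": 45}},
    {"name": "gp_home_visits", "type": "categorical",
     "counts": {"home_visits": 39, "no_home_visits": 54, "not_available": 23}},
    {"name": "home_care_services", "type": "categorical",
     "counts": {"public": 33, "private": 41, "none": 42}},
    {"name": "migrant_care_workers", "type": "categorical",
     "counts": {"provided": 3, "not_provided": 113}},
    {"name": "days_at_home_60", "type": "integer",
     "mean": 48, "min": 0, "max": 60, "attain_extremes": false},
    {"name": "days_in_hospital_60", "type": "integer",
     "mean": 10, "min": 0, "max": 60, "attain_extremes": false},
    {"name": "days_in_nursing_home_60", "type": "integer",
     "mean": 0, "min": 0, "max": 60, "attain_extremes": false},
    {"name": "hospitalisations_60", "type": "integer",
     "mean": 1, "min": 0, "max": 3, "attain_extremes": true},
    {"name": "karnofsky", "type": "categorical",
     "counts": {"10-40": 41, "50-60": 63, "70-100": 12}},
    {"name": "symptom_burden", "type": "categorical",
     "counts": {"none_low": 6, "medium": 36, "high": 74}},
    {"name": "cancer_treatment", "type": "categorical",
     "counts": {"ongoing": 67, "discontinued": 49}},
    {"name": "patient_awareness", "type": "categorical",
     "counts": {"open": 81, "closed": 34, "not_assessed": 1}},
    {"name": "patient_preference", "type": "categorical",
     "counts": {"home": 34, "hospital": 9, "nursing_home": 1,
                "not_assessed": 72}},
    {"name": "family_awareness", "type": "categorical",
     "counts": {"open": 87, "closed": 18, "not_assessed": 11}},
    {"name": "family_conditions", "type": "categorical",
     "counts": {"suitable": 39, "unsuitable": 75, "not_assessed": 2}},
    {"name": "family_preference", "type": "categorical",
     "counts": {"home": 29, "hospital": 20, "nursing_home": 1,
                "not_assessed": 66}},
    {"name": "care_team_prediction", "type": "categorical",
     "counts": {"home": 39, "nursing_home": 2, "hospital": 75}}
  ]
}
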