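{
  "drugs": [
    {
      "product_name": "ASPIRIN 500 MG",
      "active_principles": [
        "ACETYLSALICYLIC ACID"
      ],
      "atc_code": "N02BA01"
    },
    {
      "product_name": "WARFARIN 2.5 MG",
      "active_principles": [
        "WARFARIN"
      ],
      "atc_code": "B01AA03"
    },
    {
      "product_name": "DIGOXIN 0.25 MG",
      "active_principles": [
        "DIGOXIN"
      ],
      "atc_code": "C01AA05"
    },
    {
      "product_name": "MYLANTA PLUS",
      "active_principles": [
        "ALUMINUM HYDROXIDE",
        "MAGNESIUM HYDROXIDE",
        "SIMETHICONE"
      ],
      "atc_code": "A02AD01"
    },
    {
      "product_name": "ATORVASTATIN CALCIUM 20 MG",
      "active_principles": [
        "ATORVASTATIN"
      ],
      "atc_code": "C10AA05",
      "contraindicated_conditions": [
        "severe_hepatic_disease"
      ]
    },
    {
      "product_name": "SIMVASTATIN 20 MG",
      "active_principles": [
        "SIMVASTATIN"
      ],
      "atc_code": "C10AA01",
      "contraindicated_conditions": [
        "severe_hepatic_disease"
      ]
    },
    {
      "product_name": "AZITHROMYCIN SUSPENSION 200 MG",
      "active_principles": [
        "AZITHROMYCIN"
      ],
      "atc_code": "J01FA10",
      "max_daily_dose_per_kg": 10,
      "min_daily_dose_per_kg": 5
    },
    {
      "product_name": "OMEPRAZOLE 20 MG",
      "active_principles": [
        "OMEPRAZOLE"
      ],
      "atc_code": "A02BC01",
      "food_relation": "empty_stomach",
      "food_lead_min": 30,
      "food_lag_min": 0
    },
    {
      "product_name": "AMOXICILLIN 250 MG",
      "active_principles": [
        "AMOXICILLIN"
      ],
      "atc_code": "J01CA04",
      "max_daily_dose_per_kg": 90
    },
    {
      "product_name": "CARBAMAZEPINE 200 MG",
      "active_principles": [
        "CARBAMAZEPINE"
      ],
      "atc_code": "N03AF01",
      "contraindicated_conditions": [
        "pregnancy"
      ]
    },
    {
      "product_name": "ALENDRONATE SODIUM 70 MG",
      "active_principles": [
        "ALENDRONIC ACID"
      ],
      "atc_code": "M05BA04",
      "food_relation": "empty_stomach",
      "food_lead_min": 30,
      "food_lag_min": 0,
      "administration_observations": [
        "Take upon waking with a full glass of water",
        "Remain standing for at least 20 min after taking"
      ]
    },
    {
      "product_name": "LEVOTHYROXINE 50 MCG",
      "active_principles": [
        "LEVOTHYROXINE SODIUM"
      ],
      "atc_code": "H03AA01",
      "food_relation": "empty_stomach",
      "food_lead_min": 30,
      "food_lag_min": 0,
      "administration_observations": [
        "Take at least 30 min before the first meal of the day"
      ]
    },
    {
      "product_name": "PARACETAMOL 500 MG",
      "active_principles": [
        "PARACETAMOL"
      ],
      "atc_code": "N02BE01"
    },
    {
      "product_name": "TYLENOL 750 MG",
      "active_principles": [
        "PARACETAMOL"
      ],
      "atc_code": "N02BE01"
    },
    {
      "product_name": "METFORMIN 500 MG",
      "active_principles": [
        "METFORMIN"
      ],
      "atc_code": "A10BA02",
      "food_relation": "with_food",
      "food_lead_min": 15,
      "food_lag_min": 60
    },
    {
      "product_name": "LOSARTAN 50 MG",
      "active_principles": [
        "LOSARTAN POTASSIUM"
      ],
      "atc_code": "C09CA01"
    },
    {
      "product_name": "AMLODIPINE 5 MG",
      "active_principles": [
        "AMLODIPINE"
      ],
      "atc_code": "C08CA01"
    },
    {
      "product_name": "CETIRIZINE 10 MG",
      "active_principles": [
        "CETIRIZINE"
      ],
      "atc_code": "R06AE07"
    },
    {
      "product_name": "FOLIC ACID 5 MG",
      "active_principles": [
        "FOLIC ACID"
      ],
      "atc_code": "B03BB01"
    },
    {
      "product_name": "ENALAPRIL 10 MG",
      "active_principles": [
        "ENALAPRIL MALEATE"
      ],
      "atc_code": "C09AA02"
    },
    {
      "product_name": "METOPROLOL 50 MG",
      "active_principles": [
        "METOPROLOL TARTRATE"
      ],
      "atc_code": "C07AB02"
    }
  ],
  "interactions": [
    {
      "principle_a": "ACETYLSALICYLIC ACID",
      "principle_b": "WARFARIN",
      "rule_type": "NU",
      "message": "concomitant use increases bleeding risk"
    },
    {
      "principle_a": "DIGOXIN",
      "principle_b": "ALUMINUM HYDROXIDE",
      "rule_type": "S",
      "min_interval": 120,
      "message": "antacids reduce digoxin absorption"
    },
    {
      "principle_a": "ALENDRONIC ACID",
      "principle_b": "LEVOTHYROXINE SODIUM",
      "rule_type": "S",
      "min_interval": 30,
      "message": "separate administration to preserve absorption"
    }
  ],
  "food_tokens": [
    "FOOD",
    "MEAL"
  ]
}
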