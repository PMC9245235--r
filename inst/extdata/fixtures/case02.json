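{
  "case_id": "case02",
  "patient": {
    "age": 35,
    "weight": 70,
    "sex": "F",
    "conditions": []
  },
  "routine": {
    "wake_time": "07:00",
    "sleep_time": "22:00",
    "busy_intervals": [
      [
        "08:00",
        "12:00"
      ],
      [
        "13:00",
        "18:00"
      ]
    ],
    "meal_times": [
      {
        "label": "breakfast",
        "time": "07:30"
      },
      {
        "label": "lunch",
        "time": "12:30"
      },
      {
        "label": "dinner",
        "time": "19:00"
      }
    ]
  },
  "prescription": [
    {
      "drug": "PARACETAMOL 500 MG",
      "dose_amount": 500,
      "doses_per_day": 3
    },
    {
      "drug": "LOSARTAN 50 MG",
      "dose_amount": 50,
      "doses_per_day": 1
    },
    {
      "drug": "AMLODIPINE 5 MG",
      "dose_amount": 5,
      "doses_per_day": 1
    }
  ],
  "planted": {
    "error_class": "daytime_routine",
    "expected_alert_types": [],
    "expected_feasible": true
  }
}
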