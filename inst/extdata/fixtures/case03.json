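{
  "case_id": "case03",
  "patient": {
    "age": 42,
    "weight": 80,
    "sex": "M",
    "conditions": []
  },
  "routine": {
    "wake_time": "14:30",
    "sleep_time": "07:30",
    "busy_intervals": [
      [
        "22:00",
        "06:00"
      ]
    ],
    "meal_times": [
      {
        "label": "breakfast",
        "time": "15:00"
      },
      {
        "label": "dinner",
        "time": "21:00"
      },
      {
        "label": "supper",
        "time": "06:30"
      }
    ]
  },
  "prescription": [
    {
      "drug": "LOSARTAN 50 MG",
      "dose_amount": 50,
      "doses_per_day": 1
    },
    {
      "drug": "PARACETAMOL 500 MG",
      "dose_amount": 500,
      "doses_per_day": 3
    }
  ],
  "planted": {
    "error_class": "night_routine",
    "expected_alert_types": [],
    "expected_feasible": true
  }
}
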