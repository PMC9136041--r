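[
  {
    "name": "IPBS_vs_PST",
    "comparison": ["IPBS", "PST"],
    "terms": [
      {"metabolite_id": "3-(3-Hydroxyphenyl)-3-hydroxypropanoic acid", "weight": 0.00000028},
      {"metabolite_id": "1,2-Ethanediol,1-(3-methoxy-4-(sulfooxy) phenyl)", "weight": -0.000003},
      {"metabolite_id": "anserine", "weight": 0.000007},
      {"metabolite_id": "FFA (18:5)", "weight": -0.000056},
      {"metabolite_id": "benzamide", "weight": -0.000041}
    ]
  },
  {
    "name": "IPBS_vs_PQS",
    "comparison": ["IPBS", "PQS"],
    "terms": [
      {"metabolite_id": "N6-acetyl-L-lysine", "weight": -0.000003},
      {"metabolite_id": "Gly Leu", "weight": 0.000004},
      {"metabolite_id": "benzamide", "weight": -0.000032},
      {"metabolite_id": "cytidine 5'-diphosphocholine", "weight": 0.000017}
    ]
  },
  {
    "name": "IPBS_vs_PQD",
    "comparison": ["IPBS", "PQD"],
    "terms": [
      {"metabolite_id": "Ile-Phe", "weight": 0.0000006},
      {"metabolite_id": "glycohyocholic acid", "weight": 0.000044},
      {"metabolite_id": "oxypurinol", "weight": -0.000005},
      {"metabolite_id": "phenoxyacetic acid", "weight": -0.0000007},
      {"metabolite_id": "3,4,5-trimethoxycinnamic acid", "weight": 0.000117},
      {"metabolite_id": "7,8-dihydro-L-biopterin", "weight": -0.000014}
    ]
  }
]
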