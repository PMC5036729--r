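{
  "alternatives": ["x1", "x2", "x3", "x4", "x5"],
  "criteria": [
    {"name": "technical", "weight": 0.4},
    {"name": "economic", "weight": 0.35},
    {"name": "social_environmental", "weight": 0.25}
  ],
  "relations": {
    "technical": [
      ["0.5,0.5", "5/8,1/5", "7/8,0.1", "3/4,1/8", "0.5,1/6"],
      ["1/5,5/8", "0.5,0.5", "5/8,1/5", "2/3,1/6", "3/8,0.5"],
      ["0.1,7/8", "1/5,5/8", "0.5,0.5", "0.5,3/8", "1/5,5/8"],
      ["1/8,3/4", "1/6,2/3", "3/8,0.5", "0.5,0.5", "3/7,3/7"],
      ["1/6,0.5", "0.5,3/8", "5/8,1/5", "3/7,3/7", "0.5,0.5"]
    ],
    "economic": [
      ["0.5,0.5", "3/4,1/8", "6/7,0.1", "7/8,0.1", "5/8,1/5"],
      ["1/8,3/4", "0.5,0.5", "3/4,1/8", "5/8,1/4", "3/7,3/7"],
      ["0.1,6/7", "1/8,3/4", "0.5,0.5", "6/7,1/8", "3/8,0.5"],
      ["0.1,7/8", "1/4,5/8", "1/8,6/7", "0.5,0.5", "4/7,3/8"],
      ["1/5,5/8", "3/7,3/7", "0.5,3/8", "3/8,4/7", "0.5,0.5"]
    ],
    "social_environmental": [
      ["0.5,0.5", "3/5,1/3", "2/3,1/4", "3/4,1/5", "5/7,1/7"],
      ["1/3,3/5", "0.5,0.5", "3/5,2/7", "5/7,1/4", "4/7,2/7"],
      ["1/4,2/3", "2/7,3/5", "0.5,0.5", "4/7,2/7", "3/7,3/7"],
      ["1/5,3/4", "1/4,5/7", "2/7,4/7", "0.5,0.5", "3/7,0.5"],
      ["1/7,5/7", "2/7,4/7", "3/7,3/7", "0.5,3/7", "0.5,0.5"]
    ]
  }
}
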