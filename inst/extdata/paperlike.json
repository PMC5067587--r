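{
  "comment": "Illustrative five-stage qPCR study: 8 novel + 8 traditional reference candidates with an instability ladder spanning very stable to unstable, plus a low-abundance Wnt4-like target with a monotone stage trend. Qualitative, not a numeric claim about any real dataset.",
  "genes": [
    {"name": "Prdx1",  "base_ct": 19.5, "instability_sd": 0.10},
    {"name": "Phf7",   "base_ct": 26.0, "instability_sd": 0.12},
    {"name": "Ctbp1",  "base_ct": 22.5, "instability_sd": 0.14},
    {"name": "Tbp",    "base_ct": 25.0, "instability_sd": 0.22},
    {"name": "Rpl13a", "base_ct": 17.5, "instability_sd": 0.25},
    {"name": "Hprt",   "base_ct": 22.0, "instability_sd": 0.28},
    {"name": "Sugp2",  "base_ct": 24.5, "instability_sd": 0.32},
    {"name": "Gapdh",  "base_ct": 18.0, "instability_sd": 0.35},
    {"name": "Clock",  "base_ct": 25.5, "instability_sd": 0.38},
    {"name": "Usp7",   "base_ct": 24.0, "instability_sd": 0.40},
    {"name": "Taf11",  "base_ct": 26.5, "instability_sd": 0.42},
    {"name": "18S",    "base_ct": 9.0,  "instability_sd": 0.45},
    {"name": "Sdha",   "base_ct": 23.0, "instability_sd": 0.55},
    {"name": "Actb",   "base_ct": 17.0, "instability_sd": 0.70},
    {"name": "Hmbs",   "base_ct": 26.0, "instability_sd": 0.80},
    {"name": "Arpc3",  "base_ct": 21.0, "instability_sd": 0.90,
     "stage_effects": {"P14": 1.5}},
    {"name": "Wnt4",   "base_ct": 29.0, "instability_sd": 0.15,
     "stage_effects": {"P14": 0, "P28": -0.5, "P35": -1.0, "P42": -1.5, "P56": -2.0}}
  ],
  "stages": {"P14": 3, "P28": 3, "P35": 3, "P42": 3, "P56": 3},
  "loading_sd": 0.5,
  "tech_sd": 0.25,
  "replicates": 3,
  "efficiency": {"Prdx1": 1.95, "Phf7": 1.98, "Ctbp1": 1.92, "Wnt4": 1.97},
  "seed": 20161018
}
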