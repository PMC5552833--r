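{
  "insulin_map": {
    "A10AC01": "human",
    "A10AB01": "human",
    "A10AD01": "human",
    "A10AE01": "human",
    "A10AF01": "human",
    "A10AE04": "glargine",
    "A10AE05": "detemir"
  },
  "site_map": {
    "C33": "lung",
    "C34": "lung",
    "C43": "melanoma",
    "C67": "bladder",
    "C18": "colorectal",
    "C19": "colorectal",
    "C20": "colorectal",
    "C21": "colorectal",
    "C82": "nhl",
    "C83": "nhl",
    "C84": "nhl",
    "C85": "nhl",
    "C86": "nhl",
    "C884": "nhl",
    "C50": "breast",
    "C54": "endometrial",
    "C61": "prostate",
    "C22": "liver",
    "C25": "pancreas",
    "C44": "nmsc"
  },
  "comed_map": {
    "A10B": "niad",
    "C10A": "statin",
    "M01A": "nsaid",
    "G03": "hrt"
  }
}
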