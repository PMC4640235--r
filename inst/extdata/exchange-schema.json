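{
  "comment": "Machine-readable vocabulary of the mrsxml exchange format. The validator and the readers both resolve element/attribute names from this file, so they cannot drift apart. Unknown elements are rejected, which makes the format anonymizing by construction: there is no place for patient identifiers to ride along.",
  "root": "DATASET",
  "dataset_children": ["Preprocessing", "Voxel", "Grid"],
  "steps": [
    "SetReference", "Apodize", "WaterFiltering", "BaselineCorrection",
    "ChangePoints", "SetToZero", "Normalization", "AlignmentCorrection",
    "OutputRange"
  ],
  "preprocessing_children": [
    "SetReference", "Apodize", "WaterFiltering", "BaselineCorrection",
    "ChangePoints", "SetToZero", "Normalization", "AlignmentCorrection",
    "OutputRange", "AdditionalInformation"
  ],
  "additional_information_children": [
    "Name", "Place", "Date", "Label", "Keywords", "MetaData"
  ],
  "keywords_children": ["Keyword"],
  "step_children": {
    "SetReference": [],
    "Apodize": [],
    "WaterFiltering": ["Region"],
    "BaselineCorrection": ["Region"],
    "ChangePoints": ["Range"],
    "SetToZero": ["Region"],
    "Normalization": [],
    "AlignmentCorrection": ["Peak", "Noise"],
    "OutputRange": ["Range"]
  },
  "voxel_children": ["Label", "SNR", "Data"],
  "voxel_attributes": [
    "points", "storage", "ppmFirst", "ppmStep",
    "transmitterFrequency", "nucleus", "Xaxis", "Yaxis", "Zaxis"
  ],
  "grid_attributes": ["rows", "cols"],
  "grid_children": ["Voxel"],
  "storage_values": ["complex", "real"],
  "keyword_max_chars": 45,
  "zaxis_fixed": 1,
  "default_label": "***"
}
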