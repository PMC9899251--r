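[
  {
    "name": "PTW-34001 Roos",
    "geometry": "plane-parallel",
    "volume_cm3": 0.35,
    "spacing_mm": 2.0,
    "n_dw_gy_per_c": 1.0e8,
    "k_q": 1.0,
    "calibration_lab": "NPL",
    "operating_voltage_V": -400,
    "placeholder": true,
    "comment": "N_Dw and k_Q are placeholder, non-physical values; real coefficients come from the calibration certificate and TRS-398 tables."
  },
  {
    "name": "PTW-30013 Farmer",
    "geometry": "cylindrical",
    "volume_cm3": 0.6,
    "n_dw_gy_per_c": 1.0e8,
    "k_q": 1.0,
    "calibration_lab": "NPL",
    "operating_voltage_V": -400,
    "placeholder": true
  },
  {
    "name": "PTW-34045 Advanced Markus",
    "geometry": "plane-parallel",
    "volume_cm3": 0.02,
    "spacing_mm": 1.0,
    "n_dw_gy_per_c": 1.0e9,
    "k_q": 1.0,
    "calibration_lab": "NIST",
    "operating_voltage_V": -400,
    "placeholder": true
  },
  {
    "name": "IBA PPC05 #948",
    "geometry": "plane-parallel",
    "volume_cm3": 0.05,
    "spacing_mm": 0.6,
    "n_dw_gy_per_c": 1.0e9,
    "k_q": 1.0,
    "calibration_lab": "NIST",
    "operating_voltage_V": -400,
    "placeholder": true
  },
  {
    "name": "IBA PPC05 #1109",
    "geometry": "plane-parallel",
    "volume_cm3": 0.05,
    "spacing_mm": 0.6,
    "n_dw_gy_per_c": 1.0e9,
    "k_q": 1.0,
    "calibration_lab": "NPL",
    "operating_voltage_V": -400,
    "placeholder": true
  }
]
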