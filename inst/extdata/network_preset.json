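{
  "branches": [
    {
      "label": "innominate",
      "a": 10000000000000,
      "b": -8000000,
      "r2": 50000000,
      "c": 1.88e-09
    },
    {
      "label": "carotid",
      "a": 20000000000000,
      "b": -5000000,
      "r2": 100000000,
      "c": 1.98e-09
    },
    {
      "label": "subclavian",
      "a": 10000000000000,
      "b": -8000000,
      "r2": 10000000,
      "c": 3.06e-09
    },
    {
      "label": "descending_aorta",
      "a": 800000000000,
      "b": -10000000,
      "r2": 25000000,
      "c": 1.48e-09
    }
  ],
  "terminal": {
    "r_t": 80000000,
    "c_t": 3.6e-12
  },
  "p_atrium_mmHg": 8,
  "fluid": {
    "rho": 1000,
    "mu": 0.001
  },
  "r_internal": {
    "innominate": 1000000,
    "carotid": 1000000,
    "subclavian": 1000000,
    "descending_aorta": 1000000
  },
  "inlet_diameter_m": 0.012
}
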