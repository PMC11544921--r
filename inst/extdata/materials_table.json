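{
  "skin": {
    "young_modulus": 10.69, "young_modulus_sd": 0.46,
    "tangent_modulus": null,
    "yield_stress": 0.53, "yield_stress_sd": 0.12,
    "density": 960, "density_sd": 30,
    "poisson_ratio": 0.30
  },
  "flesh": {
    "young_modulus": 1.57, "young_modulus_sd": 0.12,
    "tangent_modulus": 0.92, "tangent_modulus_sd": 0.06,
    "yield_stress": 0.26, "yield_stress_sd": 0.07,
    "density": 1030, "density_sd": 45,
    "poisson_ratio": 0.40
  },
  "core": {
    "young_modulus": 5.11, "young_modulus_sd": 0.28,
    "tangent_modulus": 0.83, "tangent_modulus_sd": 0.04,
    "yield_stress": 1.12, "yield_stress_sd": 0.23,
    "density": 1120, "density_sd": 70,
    "poisson_ratio": 0.40
  },
  "steel": {
    "young_modulus": 2.1e5,
    "tangent_modulus": null,
    "yield_stress": 235,
    "density": 7850,
    "poisson_ratio": 0.33
  },
  "pvc": {
    "young_modulus": 70,
    "tangent_modulus": null,
    "yield_stress": null,
    "density": 60,
    "poisson_ratio": 0.30
  },
  "neoprene": {
    "young_modulus": 7.8,
    "tangent_modulus": null,
    "yield_stress": null,
    "density": 930,
    "poisson_ratio": 0.47
  }
}
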