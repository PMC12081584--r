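{
  "comment": "Reference parameterization of the integrated oscillator model of the pancreatic beta-cell (glycolytic oscillator + nucleotide dynamics + calcium handling + membrane electrical activity). Units: time ms, voltage mV, conductance pS, current fA, capacitance fF, concentrations uM, fluxes uM/ms. Calibrated to the slow-bursting operating regime at stimulatory glucose (calcium oscillations with a period of several minutes) near the upper glucose boundary of the oscillatory window; see the methods vignette for the calibration rationale.",
  "membrane": {
    "gca": 1000, "gk": 2700, "gkca": 150, "gkatpbar": 100000,
    "vca": 25, "vk": -75, "cm": 5300,
    "vm": -20, "sm": 12, "vn": -16, "sn": 5, "taun": 20, "kd": 0.5
  },
  "calcium": {
    "fca": 0.01, "alpha": 4.5e-6, "kpmca": 0.2,
    "kserca": 0.4, "pleak": 2e-4, "sigmav": 31
  },
  "metabolism": {
    "Jgk": 0.00146, "vpfk": 0.01, "kpfk": 0.06,
    "k1": 30, "k2": 1, "k3": 50000, "k4": 1000,
    "famp": 0.02, "fatp": 20, "ffbp": 0.2, "fbt": 20, "fmt": 20,
    "vpdh": 0.001, "kcapdh": 1e-6,
    "atot": 3000, "taua": 100000, "r_exch": 3.5, "r1": 0.35,
    "vg": 3, "kg": 0.003
  },
  "katp": {
    "fmgadp": 0.165, "fadp3": 0.135, "fatp4": 0.05,
    "kdd": 17, "ktd": 26, "ktt": 1
  },
  "initial_state": {
    "v": -60, "n": 0.01, "c": 0.1, "cer": 150,
    "f6p": 300, "fbp": 2, "adp": 120
  }
}
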