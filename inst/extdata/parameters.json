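{
  "units": {
    "concentration": "uM",
    "time": "min",
    "first_order_rate": "1/min",
    "second_order_rate": "1/(uM*min)"
  },
  "notes": "Nominal rate constants and initial pools for the TNF->IKK->IkBa->NF-kB model. Values are drawn from the canonical Lipniacki-family NF-kB parameterization (converted to per-minute units), with IkBa synthesis/turnover adjusted to the faster free-IkBa degradation reported by O'Dea-type measurements, and calibrated so the nominal model reproduces the experimentally described population dynamics in BV2 microglia: IKK activity peaking near 5 min, nuclear NF-kB peaking 15-30 min, total IkBa dipping at ~20 min before overshooting, and near-undetectable phospho-IkBa at rest.",
  "parameters": {
    "ka": {
      "value": 0.3,
      "units": "1/min",
      "description": "TNF-dependent activation of neutral IKK (IKKn -> IKKa)",
      "provenance": "lipniacki-family, calibrated"
    },
    "ki": {
      "value": 0.12,
      "units": "1/min",
      "description": "spontaneous (auto-phosphorylation) inactivation of active IKK (IKKa -> IKKi)",
      "provenance": "lipniacki-family, calibrated"
    },
    "kiA20": {
      "value": 0.044,
      "units": "1/(uM*min)",
      "description": "A20-dependent inactivation of active IKK",
      "provenance": "lipniacki-family, calibrated"
    },
    "kp": {
      "value": 0.01,
      "units": "1/min",
      "description": "recovery of inactivated IKK to the neutral state (IKKi -> IKKn)",
      "provenance": "lipniacki-family, calibrated"
    },
    "kc1a": {
      "value": 1.0,
      "units": "1/(uM*min)",
      "description": "IKKa-catalyzed phosphorylation of free IkBa",
      "provenance": "lipniacki-family, calibrated"
    },
    "kc2a": {
      "value": 5.0,
      "units": "1/(uM*min)",
      "description": "IKKa-catalyzed phosphorylation of IkBa in the IkBa:NF-kB complex",
      "provenance": "lipniacki-family, calibrated"
    },
    "kua1": {
      "value": 1.5,
      "units": "1/min",
      "description": "E3-ligase recruitment to phospho-IkBa (free and complexed)",
      "provenance": "assigned, calibrated"
    },
    "kuc1": {
      "value": 1.5,
      "units": "1/min",
      "description": "poly-ubiquitination of E3-engaged phospho-IkBa",
      "provenance": "assigned, calibrated"
    },
    "kupd": {
      "value": 0.8,
      "units": "1/min",
      "description": "proteasomal degradation of poly-ubiquitinated IkBa (releases NF-kB from complexed forms)",
      "provenance": "assigned, calibrated"
    },
    "kdp": {
      "value": 0.02,
      "units": "1/min",
      "description": "constitutive degradation of phosphorylated/ubiquitinated IkBa intermediates (model modification 1)",
      "provenance": "assigned"
    },
    "a4": {
      "value": 30.0,
      "units": "1/(uM*min)",
      "description": "association of IkBa with NF-kB (cytoplasm and nucleus)",
      "provenance": "lipniacki-family"
    },
    "d4": {
      "value": 0.008,
      "units": "1/min",
      "description": "dissociation of the IkBa:NF-kB complex",
      "provenance": "assigned"
    },
    "c6a": {
      "value": 0.0015,
      "units": "1/min",
      "description": "slow constitutive degradation of IkBa within the complex (releases NF-kB)",
      "provenance": "odea-adjusted"
    },
    "i1": {
      "value": 0.15,
      "units": "1/min",
      "description": "nuclear import of free NF-kB",
      "provenance": "lipniacki-family, calibrated"
    },
    "i1a": {
      "value": 0.05,
      "units": "1/min",
      "description": "nuclear import of free IkBa",
      "provenance": "lipniacki-family"
    },
    "e1a": {
      "value": 0.02,
      "units": "1/min",
      "description": "nuclear export of free IkBa",
      "provenance": "lipniacki-family"
    },
    "i2a": {
      "value": 0.01,
      "units": "1/min",
      "description": "nuclear import of the cytoplasmic IkBa:NF-kB complex (model modification 2)",
      "provenance": "assigned"
    },
    "e2a": {
      "value": 0.5,
      "units": "1/min",
      "description": "nuclear export of the nuclear IkBa:NF-kB complex",
      "provenance": "lipniacki-family, calibrated"
    },
    "c1a": {
      "value": 0.07,
      "units": "1/min",
      "description": "NF-kB-driven transcription of IkBa mRNA (per uM nuclear NF-kB)",
      "provenance": "assigned, calibrated"
    },
    "c2a": {
      "value": 0.5,
      "units": "1/min",
      "description": "translation of IkBa protein from IkBa mRNA",
      "provenance": "odea-adjusted, calibrated"
    },
    "c3a": {
      "value": 0.02,
      "units": "1/min",
      "description": "degradation of IkBa mRNA",
      "provenance": "lipniacki-family"
    },
    "c5a": {
      "value": 0.12,
      "units": "1/min",
      "description": "constitutive degradation of free IkBa (fast, O'Dea-type half-life ~6 min)",
      "provenance": "odea-adjusted"
    },
    "c1": {
      "value": 0.1,
      "units": "1/min",
      "description": "NF-kB-driven transcription of A20 mRNA (per uM nuclear NF-kB)",
      "provenance": "assigned, calibrated"
    },
    "c2": {
      "value": 1.0,
      "units": "1/min",
      "description": "translation of A20 protein from A20 mRNA",
      "provenance": "assigned, calibrated"
    },
    "c3": {
      "value": 0.02,
      "units": "1/min",
      "description": "degradation of A20 mRNA",
      "provenance": "lipniacki-family"
    },
    "c5": {
      "value": 0.07,
      "units": "1/min",
      "description": "degradation of A20 protein",
      "provenance": "assigned, calibrated"
    }
  },
  "pools": {
    "NFkB_total": {
      "value": 0.06,
      "units": "uM",
      "description": "total NF-kB pool, initialized entirely as cytoplasmic IkBa:NF-kB complex ([IkBaNFkB(0)])",
      "provenance": "lipniacki-family"
    },
    "IKK_total": {
      "value": 0.2,
      "units": "uM",
      "description": "total IKK pool, initialized entirely as neutral IKK ([IKKn(0)])",
      "provenance": "lipniacki-family"
    }
  }
}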