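{
  "schema": "tvfb-norm-cards/1",
  "note": "Adjusted score = raw score minus sum of coef * (transform(predictor) - center); sex is sign-coded (+1 M, -1 F). 'cuts' are the upper bounds of Equivalent-Score bands 0-3; scores above the last cut are ES 4.",
  "cards": [
    {
      "measure": "pvf_f",
      "terms": [
        {
          "predictor": "education",
          "transform": "identity",
          "coef": 0.581857,
          "center": 13.41791
        }
      ],
      "n": 335,
      "otl": 6.24,
      "itl": 8.92,
      "cuts": [6.24, 10.15, 12.33, 14.83],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "pvf_a",
      "terms": [
        {
          "predictor": "education",
          "transform": "identity",
          "coef": 0.546721,
          "center": 13.41791
        }
      ],
      "n": 335,
      "otl": 5.23,
      "itl": 7.04,
      "cuts": [5.23, 7.78, 10.49, 13.32],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "pvf_s",
      "terms": [
        {
          "predictor": "education",
          "transform": "sqrt",
          "coef": 3.459879,
          "center": 3.621862
        }
      ],
      "n": 335,
      "otl": 5.69,
      "itl": 8.06,
      "cuts": [5.69, 9.06, 11.75, 14.55],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "pvf",
      "terms": [
        {
          "predictor": "education",
          "transform": "sqrt",
          "coef": 11.19203,
          "center": 3.621862
        }
      ],
      "n": 335,
      "otl": 21.18,
      "itl": 26.05,
      "cuts": [21.18, 28.18, 35.05, 42.77],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "svf_col",
      "terms": [
        {
          "predictor": "age",
          "transform": "cube",
          "coef": -8e-06,
          "center": 165449.256716
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 4.337454,
          "center": 1.106749
        },
        {
          "predictor": "sex",
          "transform": "sign",
          "coef": -0.549597,
          "center": 0
        }
      ],
      "n": 335,
      "otl": 9.8,
      "itl": 10.91,
      "cuts": [9.8, 11.62, 13.81, 15.51],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "svf_ani",
      "terms": [
        {
          "predictor": "age",
          "transform": "cube",
          "coef": -8e-06,
          "center": 165449.256716
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 14.77632,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 11.25,
      "itl": 14.39,
      "cuts": [11.25, 15.4, 18.81, 22.69],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "svf_fru",
      "terms": [
        {
          "predictor": "age",
          "transform": "cube",
          "coef": -7e-06,
          "center": 165449.256716
        },
        {
          "predictor": "education",
          "transform": "sqrt",
          "coef": 2.030476,
          "center": 3.621862
        },
        {
          "predictor": "sex",
          "transform": "sign",
          "coef": -1.191156,
          "center": 0
        }
      ],
      "n": 335,
      "otl": 9.36,
      "itl": 11.08,
      "cuts": [9.36, 11.9, 14.07, 16.81],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "svf",
      "terms": [
        {
          "predictor": "age",
          "transform": "cube",
          "coef": -2.3e-05,
          "center": 165449.256716
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 26.77201,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 35.09,
      "itl": 39.23,
      "cuts": [35.09, 41.26, 47.84, 56.33],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "avf_acol",
      "terms": [
        {
          "predictor": "age",
          "transform": "square",
          "coef": -0.000765,
          "center": 2698.337313
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 12.67585,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 5.46,
      "itl": 7,
      "cuts": [5.46, 8.01, 11.11, 13.92],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "avf_fani",
      "terms": [
        {
          "predictor": "age",
          "transform": "square",
          "coef": -0.000731,
          "center": 2698.337313
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 14.25557,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 5.75,
      "itl": 7.93,
      "cuts": [5.75, 8.98, 11.49, 14.29],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "avf_sfru",
      "terms": [
        {
          "predictor": "age",
          "transform": "cube",
          "coef": -1e-05,
          "center": 165449.256716
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 10.65985,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 6.47,
      "itl": 8.37,
      "cuts": [6.47, 9.43, 11.83, 14.37],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "avf",
      "terms": [
        {
          "predictor": "age",
          "transform": "square",
          "coef": -0.002323,
          "center": 2698.337313
        },
        {
          "predictor": "education",
          "transform": "log10",
          "coef": 37.46202,
          "center": 1.106749
        }
      ],
      "n": 335,
      "otl": 19.6,
      "itl": 25.91,
      "cuts": [19.6, 29.27, 35.66, 42.36],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    },
    {
      "measure": "csi",
      "terms": [
        {
          "predictor": "age",
          "transform": "square",
          "coef": -2.9e-05,
          "center": 2698.337313
        },
        {
          "predictor": "education",
          "transform": "reciprocal",
          "coef": -0.818169,
          "center": 0.083184
        }
      ],
      "n": 335,
      "otl": 0.48,
      "itl": 0.6,
      "cuts": [0.48, 0.66, 0.76, 0.86],
      "provenance": "published normative card of the telephone verbal fluency battery (Italian standardization, N = 335)"
    }
  ]
}
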