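{
  "n_counties": 50,
  "years": [1998, 1999, 2000, 2001, 2002, 2003, 2004, 2005, 2006, 2007,
            2008, 2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017],
  "weather_weeks": [20, 21, 22, 23, 24, 25, 26, 27, 28, 29],
  "progress_weeks": [20, 21, 22, 23],
  "beta0": 6,
  "beta": {
    "W_tmax_wk24": -1.2,
    "W_prcp_wk22": 0.9,
    "S_om_d0_5": 1.1,
    "M_planted_wk21": -0.5,
    "W_srad_wk26": 0.6
  },
  "interactions": [
    {"var_a": "W_prcp_wk23", "var_b": "W_tmax_wk25",
     "kernel_id": "product", "b": 2.0},
    {"var_a": "W_tmin_wk21", "var_b": "M_planted_wk22",
     "kernel_id": "product", "b": -1.6}
  ],
  "noise_sd": 0.3,
  "progress_noise_sd": 0.08,
  "trend_mean": 0,
  "trend_sd": 0,
  "seed": 1
}
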