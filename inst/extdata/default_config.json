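{
  "peak_rating": {"min_rating": 5, "min_samples": 5},
  "usable_hits": {"min_fraction": 0.8},
  "impute": {"n_trees": 100, "max_iter": 10},
  "qc_correct": {"n_trees": 200, "n_predictors": 10},
  "rsd_filter": {"max_before": 50, "max_after": 25},
  "normalize": {"reference": "max"},
  "opls": {"max_orth": 3, "n_folds": 7, "delta_q2": 0.01},
  "select": {"vip_min": 1.5, "pcorr_min": 0.5, "p_max": 0.05, "model_p_max": 0.05},
  "biotransform": {"max_depth": 2, "tol_ppm": 5},
  "network": {"min_score": 50, "min_fragments": 3, "min_coverage": 70, "frag_tol": 0.0025},
  "annotate": {"mz_tol_ppm": 5, "rt_tol_min": 0.2, "ms2_cutoff": 85}
}
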