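# Example pipeline configuration for batchtea::reproduce()
n_scenarios: 5000
seed: 42
marr: 0.30
irr_range: [0.01, 0.50]
upc_window: [140, 240]
models: [lm, knn, svr, poly_ridge, rf, xgb]
select_features: true
cv_folds: 5
tune: false
out_dir: tea_output
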