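# Item-panel preset: a 12-item binary symptom checklist (brief obsessive-
# compulsive scale style; each item endorsed = 1, never = 0).  Equal probit
# loadings are calibrated via the Spearman-Brown identity so that Cronbach
# alpha of the responses is 0.76 at the published mean inter-item
# correlation (alpha/(k - alpha (k-1)) = 0.2088), with ~30% endorsement per
# item: latent item correlation 0.3418 -> loading 0.7206069, threshold
# 0.6463700 on the loading-inflated item scale.
kind: item_panel
panel:
  n_items: 12
  loadings: 0.7206069
  item_thresholds: 0.6463700
  n_persons: 9230
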