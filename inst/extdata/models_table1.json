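[
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}],
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}, {"label": "c", "mode": "dominant"}],
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}, {"label": "c", "mode": "recessive"}],
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}, {"label": "c", "mode": "dominant"}, {"label": "d", "mode": "dominant"}],
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}, {"label": "c", "mode": "recessive"}, {"label": "d", "mode": "dominant"}],
  [{"label": "a", "mode": "recessive"}, {"label": "b", "mode": "recessive"}, {"label": "c", "mode": "recessive"}, {"label": "d", "mode": "recessive"}]
]
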