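# Example pipeline configuration: only keys that differ from the
# defaults need to be given.
dpi: 8500
filename:
  tokens: [side, ecotype_label, ecotype_index, rep_tag, replicate, batch, leaf_count]
  side_codes: {D: abaxial, G: adaxial}
  rep_tag: I
  batch_prefix: K
eggs:
  level: 0.90
feces:
  level: 0.75
pairing:
  mirror_axis: vertical
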