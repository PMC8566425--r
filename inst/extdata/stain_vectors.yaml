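# Unit optical-density stain vectors (RGB absorption) shared by the scene
# renderer and the deconvolution step. Values are normalized on load.
hematoxylin: [0.651, 0.701, 0.290]
purple: [0.180, 0.940, 0.290]
teal: [0.950, 0.150, 0.270]
yellow: [0.100, 0.210, 0.970]
background: [1.0, 1.0, 1.0]
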