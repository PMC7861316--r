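# ROI-name aliases -> canonical structure names.
# Keys are matched case-insensitively after trimming whitespace.
body: body
external: body
skin: body
ptv: ptv
gtv: gtv
spinalcord: cord
spinal cord: cord
cord: cord
"cord+3mm": "cord+3mm"
"cord+3 mm": "cord+3mm"
"spinalcord+3mm": "cord+3mm"
"cord_prv3": "cord+3mm"
lungs: lungs
lung_total: lungs
total lung: lungs
"lungs-gtv": lungs
heart: heart
esophagus: esophagus
oesophagus: esophagus
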