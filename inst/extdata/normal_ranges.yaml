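# Editable reference-range table for the automated summary.
# Generic adult placeholder ranges; replace with site-specific values.
lv_edv_ml: [100, 200]
lv_esv_ml: [30, 90]
lv_ef_percent: [52, 72]
lv_co_l_min: [3.5, 8.0]
lvm_g: [70, 180]
rv_edv_ml: [100, 220]
rv_esv_ml: [35, 100]
rv_ef_percent: [47, 74]
rv_co_l_min: [3.5, 8.0]
la_ef_percent: [30, 70]
ra_ef_percent: [25, 65]
la_fac_percent: [25, 65]
ra_fac_percent: [25, 65]
scar_percent: [0, 5]
heart_rate_bpm: [50, 100]
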