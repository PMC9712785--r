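source_id	source_regulation	target_id	target_regulation
circRNA04655	Down	miR-669f-5p	Up
circRNA00723	Down	miR-669f-5p	Up
circRNA00723	Down	miR-466i-5p	Up
circRNA03723	Up	miR-466i-5p	Up
circRNA00747	Down	miR-6240	Up
circRNA01891	Up	miR-3470b	Up
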