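individual	group
287	NE
288	NE
282	NE
257A	NW
257B	NW
243	NW
260	NW
161	SE
295	SE
181	SE
163	SE
302	SE
220	SW
225	SW
224	SW
223	SW
228	SW
237	SW
246	SW
247	SW
186	SW
211	SW
122S	SW
122E	SW
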