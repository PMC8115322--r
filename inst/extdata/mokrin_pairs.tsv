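id1	id2	degree
257A	243	first (parent-offspring)
228	260	first (parent-offspring)
163	181	first (parent-offspring)
122E	211	first (siblings)
161	295	first (siblings)
257B	257A	second
257B	243	second
220	225	second
282	288	third
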