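format-version: 1.2

[Term]
id: W:01
name: disease

[Term]
id: W:02
name: nervous system disease
is_a: W:01 ! disease

[Term]
id: W:03
name: cell proliferation disease
is_a: W:01 ! disease

[Term]
id: W:04
name: neuromuscular disease
is_a: W:02 ! nervous system disease
is_a: W:03 ! cell proliferation disease

[Term]
id: W:05
name: tauopathy
is_a: W:04 ! neuromuscular disease

[Term]
id: W:06
name: alzheimer's disease
synonym: "AD" EXACT []
synonym: "alzheimers dementia" EXACT []
is_a: W:05 ! tauopathy

[Term]
id: W:07
name: carcinoma
is_a: W:03 ! cell proliferation disease

[Term]
id: W:08
name: colorectal carcinoma
is_a: W:07 ! carcinoma

[Term]
id: W:09
name: metabolic disease
is_a: W:02 ! nervous system disease

[Term]
id: W:10
name: mixed syndrome
is_a: W:04 ! neuromuscular disease
is_a: W:09 ! metabolic disease

[Term]
id: W:11
name: frontotemporal dementia
is_a: W:05 ! tauopathy

[Term]
id: W:12
name: early-onset alzheimer's disease
is_a: W:06 ! alzheimer's disease
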