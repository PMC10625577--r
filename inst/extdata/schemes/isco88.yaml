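# Occupation classification: 4 digits (e.g. 2221); major / sub-major /
# minor / unit groups are the 1..4-digit prefixes.
name: ISCO-88
placeholder: "#"
levels: [1, 2, 3, 4]
separators: []
alphabet: ["0123456789", "0123456789", "0123456789", "0123456789"]
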