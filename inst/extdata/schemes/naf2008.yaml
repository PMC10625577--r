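# Activity-sector classification: 4 digits + 1 letter (e.g. 4231A).
# Level 1 is the 21-section grouping of the 2-digit division.
name: NAF2008
placeholder: "#"
levels: [lookup:2, 2, 3, 4, 5]
lookup_file: naf2008_sections.csv
separators: []
alphabet: ["0123456789", "0123456789", "0123456789", "0123456789", "ABCDEFGHIJKLMNOPQRSTUVWXYZ"]
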