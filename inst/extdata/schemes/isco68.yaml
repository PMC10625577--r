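# Occupation classification with canonical rendering 1-21.10: five
# significant digits, "-" after position 1 and "." after position 3.
# Partially coded entries keep only the codable levels (1-21 = 1-21.##).
name: ISCO-68
placeholder: "#"
levels: [1, 2, 3, 5]
separators: ["1:-", "3:."]
alphabet: ["0123456789", "0123456789", "0123456789", "0123456789", "0123456789"]
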