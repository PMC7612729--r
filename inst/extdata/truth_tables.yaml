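# Chromatin-state truth tables: mark-presence combination -> state.
# Keys are binary strings in the order of the `marks` list (1 = the element
# is covered >= min_overlap_frac by a peak of that mark in the cell type).
# Edit and pass to classify_elements(truth_table = read_truth_table(...))
# to change the mapping without touching code.
version: 1
enhancer:
  marks: [H3K4me1, H3K27ac, H3K27me3]
  states:
    "000": neutral
    "001": repressed
    "010": active
    "011": mixed
    "100": primed
    "101": poised
    "110": active
    "111": mixed
promoter:
  marks: [H3K4me3, H3K27ac, H3K27me3]
  states:
    "000": neutral
    "001": repressed
    "010": active
    "011": mixed
    "100": active
    "101": poised
    "110": active
    "111": mixed
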