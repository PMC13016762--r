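Place the deposited 94-taxon feather dataset here to enable the
published-table reproduction test and workflows:

  tree.nex    rooted tree topology (NEXUS)
  matrix.csv  columns: taxon, state (six-state coding; `&` ambiguity, `?`)
  ages.csv    columns: taxon, FAD, LAD (Ma)

The archive is distributed through the Dryad Digital Repository and is not
bundled with the package.
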