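# Column-name mapping for the synthetic HALO-style export shipped in
# this directory (synthetic_halo_cells.csv, generated by
# simulate_cells_table with seed 42). Real exports vary; edit the
# right-hand sides to match your files.
columns:
  section_id: "Image Tag"
  phenotype: "Phenotype"
  nuclear_area: "Nucleus Area"
  puncta: "AKT3 Copies"
  radius: "Radius"
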