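{
  "mt_rna_nacl_150mM": 54,
  "mt_rna_nacl_4M": 41,
  "mt_dna_nacl_150mM": 47,
  "mt_dna_nacl_4M": 38,
  "mt_rna_licl_150mM": 53,
  "mt_rna_licl_6M": 38,
  "mt_dna_licl_150mM": 45,
  "mt_dna_licl_6M": 39,
  "md_rna_nacl_150mM": 55,
  "md_rna_nacl_4M": 40,
  "md_dna_nacl_150mM": 48,
  "md_dna_nacl_4M": 39,
  "md_rna_licl_150mM": 54,
  "md_rna_licl_6M": 39,
  "md_dna_licl_150mM": 46,
  "md_dna_licl_6M": 39,
  "rise_dna": 0.34,
  "rise_rna": 0.28,
  "intrinsic_rna": 39,
  "intrinsic_dna": 38,
  "chargefrac_ext_rna_nacl_150mM": 0.24,
  "chargefrac_ext_dna_nacl_150mM": 0.36,
  "chargefrac_ext_rna_nacl_4M": 0.89,
  "chargefrac_ext_dna_nacl_4M": 0.91,
  "pel_rna": 17,
  "pel_dna": 10,
  "pnel_bj_rna": 38.4,
  "pnel_bj_dna": 38.5,
  "n_bp_construct": 13751
}
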