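# Synthetic placeholder gene sets for signature scoring. The published
# AR, NEPC, IFN-gamma and T-cell inflammation signatures are defined in
# their source publications and are not redistributed here; replace these
# lists with the published memberships for real analyses.
gene_sets:
  ar_signature: [KLK3, KLK2, NKX3-1, TMPRSS2, FKBP5, PART1]
  nepc_signature: [SYP, CHGA, ENO2, NCAM1, INSM1, ASCL1]
  ifng_signature: [STAT1, IDO1, CXCL9, CXCL10, HLA-DRA, GZMA]
  tcell_inflammation: [CD8A, GZMB, PRF1, CCL5, CD274, LAG3]
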