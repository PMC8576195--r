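snps:
- snp_id: rs121909567
  gene: SERPINC1
  alleles:
  - G
  - A
  risk_allele: A
- snp_id: rs1799963
  gene: F2
  alleles:
  - G
  - A
  risk_allele: A
  weight: 1.029619417181158
- snp_id: rs2036914
  gene: F11
  alleles:
  - T
  - C
  risk_allele: C
  weight: 0.300104592450338
- snp_id: rs2066865
  gene: FGG
  alleles:
  - G
  - A
  risk_allele: A
  weight: 0.22314355131421
- snp_id: rs6025
  gene: F5
  alleles:
  - C
  - T
  risk_allele: T
  weight: 1.435084525289323
- snp_id: rs8176719
  gene: ABO
  alleles:
  - C
  - DEL
  risk_allele: DEL
  weight: 0.405465108108164
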