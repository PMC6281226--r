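batches:
- batch_id: Batch3
  platform: HiSeq4000
  column_indices:
  - C01
  - C02
  - C03
  - C04
  - C05
  - C06
  - C07
  - C08
  - C09
  - C10
  - C11
  - C12
  plates:
  - plate_id: Plate4
    row_indices:
    - R01
    - R02
    - R03
    - R04
    - R05
    - R06
    - R07
    - R08
    cell_types:
    - 50 0 P T T T P T P T T P
    - T T T P T T P P T T P T
    - P T T T P P P T T 0 P T
    - T T P T P P P P P P T P
    - T 0 T T T T T T T T P T
    - X 0 P T T 0 T P P T T P
    - T P T P T P T T P T T P
    - T P T T T T T P T T P T
  - plate_id: Plate5
    row_indices:
    - R09
    - R10
    - R11
    - R12
    - R13
    - R14
    - R15
    - R16
    cell_types:
    - 50 T T T P T T T P X T P
    - T T P T P P P P T T P T
    - P P P X X P P P P T T T
    - T P T T P X T P T P T T
    - P P 0 P T P 0 T T T 0 P
    - P T T T P P T T P P T 0
    - T P P T T P P P T P T T
    - T T T 0 P P P P T P T T
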