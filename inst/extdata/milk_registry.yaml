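# Proteoform registry fixture: the 23 external/internal-standard
# proteoforms of the bovine milk panel plus the horse-myoglobin IS.
# curated_mass values are the curated theoretical monoisotopic masses
# (average mass for BSA, flagged average_only) of the printed
# deconvolution report; sequence-backed entries (fasta_id set) also
# derive exact-chemistry masses from milk_sequences.fasta.
# response_factor: EIC area units per mg/mL, from the reproducibility
# panel at 10 mg/mL (IS spiked at 0.2 mg/mL). expected_rt_min: apex
# retention times of the same panel. kCN A/B, bLG D and BSA entries
# are mass-backed (synthetic averagine composition stand-ins).
tolerance: 0.1
internal_standard: Myo
standard_groups:
  aLA: [aLA B, aLA B+G]
  aCN: [aS1CN B-8P, aS1CN B-9P, aS2CN A-10P, aS2CN A-11P, aS2CN A-12P, aS2CN A-13P,
    aS2CN A-14P]
  bCN: [bCN A1-5P, bCN A2-5P, bCN B-5P, bCN I-5P]
  bLG: [bLG A, bLG B, bLG D]
  BSA: [BSA]
  kCN: [kCN A-1P, kCN A-2P, kCN B-1P, kCN B-1P+G, kCN B-2P]
proteoforms:
- protein_code: aLA B
  fasta_id: ALA_B
  n_phospho: 0
  glycan: {}
  curated_mass: 14176.798
  average_only: false
  expected_rt_min: 15.78
  response_factor: 50120300.8
  charges: [5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19]
- protein_code: aLA B+G
  fasta_id: ALA_B
  n_phospho: 0
  glycan: {Hex: 2}
  curated_mass: 14500.902
  average_only: false
  expected_rt_min: 13.95
  response_factor: 270902.0
  charges: [5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
- protein_code: aS1CN B-8P
  fasta_id: AS1CN_B
  n_phospho: 8
  glycan: {}
  curated_mass: 23600.472
  average_only: false
  expected_rt_min: 15.28
  response_factor: 4674352.1
  charges: [12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27]
- protein_code: aS1CN B-9P
  fasta_id: AS1CN_B
  n_phospho: 9
  glycan: {}
  curated_mass: 23680.472
  average_only: false
  expected_rt_min: 17.88
  response_factor: 275761.0
  charges: [12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27]
- protein_code: aS2CN A-10P
  fasta_id: AS2CN_A
  n_phospho: 10
  glycan: {}
  curated_mass: 25133.343
  average_only: false
  expected_rt_min: 6.79
  response_factor: 645316.8
  charges: [13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28]
- protein_code: aS2CN A-11P
  fasta_id: AS2CN_A
  n_phospho: 11
  glycan: {}
  curated_mass: 25213.343
  average_only: false
  expected_rt_min: 7.08
  response_factor: 1104555.3
  charges: [14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29]
- protein_code: aS2CN A-12P
  fasta_id: AS2CN_A
  n_phospho: 12
  glycan: {}
  curated_mass: 25293.343
  average_only: false
  expected_rt_min: 7.56
  response_factor: 2048076.3
  charges: [14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29]
- protein_code: aS2CN A-13P
  fasta_id: AS2CN_A
  n_phospho: 13
  glycan: {}
  curated_mass: 25373.343
  average_only: false
  expected_rt_min: 8.03
  response_factor: 1114485.4
  charges: [14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29]
- protein_code: aS2CN A-14P
  fasta_id: AS2CN_A
  n_phospho: 14
  glycan: {}
  curated_mass: 25453.343
  average_only: false
  expected_rt_min: 8.3
  response_factor: 447231.0
  charges: [14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29]
- protein_code: bCN A1-5P
  fasta_id: BCN_A1
  n_phospho: 5
  glycan: {}
  curated_mass: 24008.317
  average_only: false
  expected_rt_min: 19.67
  response_factor: 14464182.9
  charges: [13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28]
- protein_code: bCN A2-5P
  fasta_id: BCN_A2
  n_phospho: 5
  glycan: {}
  curated_mass: 23968.311
  average_only: false
  expected_rt_min: 21.12
  response_factor: 26155227.7
  charges: [12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27]
- protein_code: bCN B-5P
  fasta_id: BCN_B
  n_phospho: 5
  glycan: {}
  curated_mass: 24077.386
  average_only: false
  expected_rt_min: 18.76
  response_factor: 5860490.8
  charges: [13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28]
- protein_code: bCN I-5P
  fasta_id: BCN_I
  n_phospho: 5
  glycan: {}
  curated_mass: 23950.355
  average_only: false
  expected_rt_min: 22.61
  response_factor: 749713.5
  charges: [12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27]
- protein_code: bLG A
  fasta_id: BLG_A
  n_phospho: 0
  glycan: {}
  curated_mass: 18355.446
  average_only: false
  expected_rt_min: 22.09
  response_factor: 24263219.7
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: bLG B
  fasta_id: BLG_B
  n_phospho: 0
  glycan: {}
  curated_mass: 18269.409
  average_only: false
  expected_rt_min: 20.64
  response_factor: 19572882.1
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: bLG D
  fasta_id: null
  n_phospho: 0
  glycan: {}
  curated_mass: 18268.41
  average_only: false
  expected_rt_min: 24.74
  response_factor: 763392.6
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: BSA
  fasta_id: null
  n_phospho: 0
  glycan: {}
  curated_mass: 66462.966
  average_only: true
  expected_rt_min: 16.53
  response_factor: 5626413.3
  charges: [48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63]
- protein_code: kCN A-1P
  fasta_id: null
  n_phospho: 1
  glycan: {}
  curated_mass: 19026.542
  average_only: false
  expected_rt_min: 6.44
  response_factor: 6107022.4
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: kCN A-2P
  fasta_id: null
  n_phospho: 2
  glycan: {}
  curated_mass: 19106.542
  average_only: false
  expected_rt_min: 8.39
  response_factor: 832989.2
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: kCN B-1P
  fasta_id: null
  n_phospho: 1
  glycan: {}
  curated_mass: 18994.589
  average_only: false
  expected_rt_min: 8.28
  response_factor: 7898945.1
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: kCN B-1P+G
  fasta_id: null
  n_phospho: 1
  glycan: {Hex: 1, HexNAc: 1, NeuAc: 1}
  curated_mass: 19650.817
  average_only: false
  expected_rt_min: 7.89
  response_factor: 495892.2
  charges: [9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24]
- protein_code: kCN B-2P
  fasta_id: null
  n_phospho: 2
  glycan: {}
  curated_mass: 19074.589
  average_only: false
  expected_rt_min: 9.81
  response_factor: 2058064.4
  charges: [8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23]
- protein_code: Myo
  fasta_id: MYO_HORSE
  n_phospho: 0
  glycan: {}
  curated_mass: 16940.956
  average_only: false
  expected_rt_min: 17.91
  response_factor: 98012845.0
  charges: [7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22]
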