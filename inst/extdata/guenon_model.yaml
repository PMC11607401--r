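populations:
  denti: 200000.0
  wolfi: 200000.0
  pogonias: 200000.0
  mona: 200000.0
  neglectus: 200000.0
  cephus: 200000.0
  nictitans: 200000.0
  mitis: 200000.0
  macaque: 200000.0
  anc_dw: 200000.0
  anc_dwp: 200000.0
  anc_mona: 200000.0
  anc_mitis: 200000.0
  anc_cm: 200000.0
  anc_cmn: 200000.0
  anc_guenon: 200000.0
  root: 200000.0
splits:
- time: 110000.0
  derived: denti
  ancestral: anc_dw
- time: 110000.0
  derived: wolfi
  ancestral: anc_dw
- time: 200000.0
  derived: anc_dw
  ancestral: anc_dwp
- time: 200000.0
  derived: pogonias
  ancestral: anc_dwp
- time: 250000.0
  derived: nictitans
  ancestral: anc_mitis
- time: 250000.0
  derived: mitis
  ancestral: anc_mitis
- time: 450000.0
  derived: anc_dwp
  ancestral: anc_mona
- time: 450000.0
  derived: mona
  ancestral: anc_mona
- time: 550000.0
  derived: anc_mitis
  ancestral: anc_cm
- time: 550000.0
  derived: cephus
  ancestral: anc_cm
- time: 650000.0
  derived: anc_cm
  ancestral: anc_cmn
- time: 650000.0
  derived: neglectus
  ancestral: anc_cmn
- time: 800000.0
  derived: anc_mona
  ancestral: anc_guenon
- time: 800000.0
  derived: anc_cmn
  ancestral: anc_guenon
- time: 1350000.0
  derived: anc_guenon
  ancestral: root
- time: 1350000.0
  derived: macaque
  ancestral: root
pulses:
- time: 100000.0
  source: mitis
  dest: denti
  phi: 0.002
- time: 270000.0
  source: cephus
  dest: anc_dwp
  phi: 0.085
- time: 310000.0
  source: anc_mitis
  dest: anc_dwp
  phi: 0.021
mu: 4.82e-09
gen_time: 10.0
ploidy_mode: autosomal
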