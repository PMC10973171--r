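type: nucleoside
code: A
name: adenosine
lambda_max: 259
eps_max: 15400
eps_260: 15020
residue_mass: 329.21
source: eps_260 from the revised ribonucleotide coefficients (AMP, pH 7); lambda_max/eps_max standard reference spectrum; residue mass = AMP free acid - H2O (average masses)

type: nucleoside
code: C
name: cytidine
lambda_max: 271
eps_max: 9100
eps_260: 7070
residue_mass: 305.18
source: eps_260 from the revised ribonucleotide coefficients (CMP, pH 7); lambda_max/eps_max standard reference spectrum; residue mass = CMP free acid - H2O

type: nucleoside
code: G
name: guanosine
lambda_max: 253
eps_max: 13700
eps_260: 12080
residue_mass: 345.21
source: eps_260 from the revised ribonucleotide coefficients (GMP, pH 7); lambda_max/eps_max standard reference spectrum; residue mass = GMP free acid - H2O

type: nucleoside
code: U
name: uridine
lambda_max: 262
eps_max: 10100
eps_260: 9660
residue_mass: 306.17
source: eps_260 from the revised ribonucleotide coefficients (UMP, pH 7); lambda_max/eps_max standard reference spectrum; residue mass = UMP free acid - H2O

type: nucleoside
code: T
name: 5-methyluridine (ribothymidine)
lambda_max: 267
eps_max: 9797
eps_260: 8558.76
residue_mass: 320.19
source: derived from uridine anchors and the thymidine comparison (+5 nm, -3% at lambda_max, -11.4% at 260 nm); residue mass = U residue + CH2

type: nucleoside
code: Y
name: pseudouridine
lambda_max: 262
eps_max: 7900
eps_260: 7532.80
residue_mass: 306.17
source: eps_260 back-computed from the m1Y value and the measured -22.8% m1Y-vs-Y difference at 260 nm; lambda_max as uridine isomer; eps_max literature-order value at pH 7.4; mass identical to U (isomer)

type: nucleoside
code: m1Y
name: N1-methylpseudouridine
lambda_max: 271
eps_max: 7979
eps_260: 5815.32
residue_mass: 320.19
source: derived from uridine anchors and the measured differences (-39.8% at 260 nm, -21% at lambda_max, +9 nm vs pseudouridine); residue mass = Y residue + CH2

type: nucleoside
code: m5C
name: 5-methylcytidine
lambda_max: 278
eps_max: 8300
eps_260: 5599.44
residue_mass: 319.21
source: derived from cytidine anchors and the measured differences (-20.8% at 260 nm, +7 nm); eps_max literature-order value at pH 7.4; residue mass = C residue + CH2

type: nucleoside
code: m7G
name: 7-methylguanosine
lambda_max: 258
eps_max: 9600
eps_260: 7400
residue_mass: 359.24
source: approximate literature values for 7-methylguanosine at neutral pH; residue mass = G residue + CH2

type: cap
code: none
eps_260_add: 0
mass_add: 0
source: uncapped construct; the 5-prime end adjustment of the molecular-weight formula applies instead

type: cap
code: cap0
eps_260_add: 7400
mass_add: 519.20
source: m7GpppN cap; epsilon contribution of the m7G chromophore; mass = m7G residue (359.24) + two bridging HPO3 (2 x 79.98)

type: cap
code: cap1
eps_260_add: 7400
mass_add: 533.23
source: m7GpppNm cap; 2-prime-O-methylation adds one CH2 (14.03) and no chromophore, so eps_260_add equals cap0
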