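# Tissue-surrogate and reference-tissue library.
#
# Mass densities (g/cm^3) and reference RSP values are the manufacturer /
# measured values for the CIRS 062M, Gammex 467-1009 and CIRS ATOM torso
# phantom inserts.  Elemental weight fractions are NOT published for these
# surrogates; the compositions below are approximations assembled from
# published vendor formulations (Gammex), epoxy-resin formulations typical
# of CIRS surrogates, and ICRU-44-style body tissues (ATOM organs).  They
# are internally consistent (fractions sum to 1) and physically plausible,
# but should not be mistaken for certified vendor data.
version: 1
materials:
- name: Water
  group: reference
  rho: 1.000
  rsp_ref: 1.000
  rho_e_ref: 1.000
  composition: {H: 0.111894, O: 0.888106}
- name: Lung (Inhale)
  group: cirs_062m
  rho: 0.203
  rsp_ref: 0.202
  composition: {H: 0.0850, C: 0.6000, "N": 0.0200, O: 0.1800, Mg: 0.1100, Si: 0.0040, Cl: 0.0010}
- name: Lung (Exhale)
  group: cirs_062m
  rho: 0.494
  rsp_ref: 0.492
  composition: {H: 0.0840, C: 0.5980, "N": 0.0200, O: 0.1820, Mg: 0.1110, Si: 0.0040, Cl: 0.0010}
- name: Adipose
  group: cirs_062m
  rho: 0.965
  rsp_ref: 0.977
  composition: {H: 0.0906, C: 0.7230, "N": 0.0225, O: 0.1627, Cl: 0.0012}
- name: Breast Tissue
  group: cirs_062m
  rho: 0.996
  rsp_ref: 1.003
  composition: {H: 0.0860, C: 0.7010, "N": 0.0233, O: 0.1790, Cl: 0.0012, Ca: 0.0095}
- name: Muscle
  group: cirs_062m
  rho: 1.059
  rsp_ref: 1.059
  composition: {H: 0.0910, C: 0.6970, "N": 0.0210, O: 0.1680, Cl: 0.0010, Ca: 0.0220}
- name: Liver
  group: cirs_062m
  rho: 1.072
  rsp_ref: 1.070
  composition: {H: 0.0900, C: 0.7000, "N": 0.0200, O: 0.1660, Cl: 0.0010, Ca: 0.0230}
- name: Bone 200 mg/cc
  group: cirs_062m
  rho: 1.157
  rsp_ref: 1.116
  composition: {H: 0.0680, C: 0.5570, "N": 0.0200, O: 0.2350, P: 0.0320, Cl: 0.0010, Ca: 0.0870}
- name: Bone 800 mg/cc
  group: cirs_062m
  rho: 1.520
  rsp_ref: 1.404
  composition: {H: 0.0490, C: 0.4030, "N": 0.0150, O: 0.3210, P: 0.0450, Cl: 0.0010, Ca: 0.1660}
- name: Bone 1250 mg/cc
  group: cirs_062m
  rho: 1.830
  rsp_ref: 1.647
  composition: {H: 0.0380, C: 0.3200, "N": 0.0160, O: 0.3620, P: 0.0600, Cl: 0.0005, Ca: 0.2035}
- name: LN450 Lung
  group: gammex_467
  rho: 0.450
  rsp_ref: 0.448
  composition: {H: 0.0847, C: 0.5957, "N": 0.0197, O: 0.1810, Mg: 0.1121, Si: 0.0058, Cl: 0.0010}
- name: Breast
  group: gammex_467
  rho: 0.980
  rsp_ref: 0.969
  composition: {H: 0.0859, C: 0.7011, "N": 0.0233, O: 0.1789, Cl: 0.0013, Ca: 0.0095}
- name: Brain
  group: gammex_467
  rho: 1.050
  rsp_ref: 1.061
  composition: {H: 0.1083, C: 0.7254, "N": 0.0169, O: 0.1486, Cl: 0.0008}
- name: Liver LV1
  group: gammex_467
  rho: 1.090
  rsp_ref: 1.090
  composition: {H: 0.0806, C: 0.6701, "N": 0.0247, O: 0.2001, Cl: 0.0014, Ca: 0.0231}
- name: B200 Bone Mineral
  group: gammex_467
  rho: 1.150
  rsp_ref: 1.099
  composition: {H: 0.0665, C: 0.5552, "N": 0.0198, O: 0.2363, P: 0.0324, Cl: 0.0011, Ca: 0.0887}
- name: CB2-50% CaCO3 Bone
  group: gammex_467
  rho: 1.560
  rsp_ref: 1.422
  composition: {H: 0.0477, C: 0.4161, "N": 0.0152, O: 0.3200, Cl: 0.0008, Ca: 0.2002}
- name: SB3 Cortical Bone
  group: gammex_467
  rho: 1.820
  rsp_ref: 1.614
  composition: {H: 0.0341, C: 0.3141, "N": 0.0184, O: 0.3649, Cl: 0.0004, Ca: 0.2681}
- name: Torso Lung
  group: atom_torso
  rho: 0.202
  rsp_ref: 0.201
  composition: {H: 0.1030, C: 0.1050, "N": 0.0310, O: 0.7490, Na: 0.0020, P: 0.0020, S: 0.0030, Cl: 0.0030, K: 0.0020}
- name: Torso Breast
  group: atom_torso
  rho: 0.991
  rsp_ref: 0.982
  composition: {H: 0.1060, C: 0.3320, "N": 0.0300, O: 0.5270, Na: 0.0010, P: 0.0010, S: 0.0020, Cl: 0.0010}
- name: Torso Soft Tissue
  group: atom_torso
  rho: 1.055
  rsp_ref: 1.041
  composition: {H: 0.1050, C: 0.2560, "N": 0.0270, O: 0.6020, Na: 0.0010, P: 0.0020, S: 0.0030, Cl: 0.0020, K: 0.0020}
- name: Torso Spinal Cord
  group: atom_torso
  rho: 1.065
  rsp_ref: 1.035
  composition: {H: 0.1080, C: 0.1400, "N": 0.0220, O: 0.7150, Na: 0.0020, P: 0.0040, S: 0.0020, Cl: 0.0040, K: 0.0030}
- name: Torso Brain
  group: atom_torso
  rho: 1.069
  rsp_ref: 1.049
  composition: {H: 0.1070, C: 0.1450, "N": 0.0220, O: 0.7120, Na: 0.0020, P: 0.0040, S: 0.0020, Cl: 0.0030, K: 0.0030}
- name: Torso Bone
  group: atom_torso
  rho: 1.517
  rsp_ref: 1.410
  composition: {H: 0.0640, C: 0.2780, "N": 0.0270, O: 0.4100, Na: 0.0010, Mg: 0.0020, P: 0.0700, S: 0.0020, Cl: 0.0010, K: 0.0010, Ca: 0.1440}
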