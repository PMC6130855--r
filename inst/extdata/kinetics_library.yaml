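# siftvoc kinetics library, schema version 1.
#
# One entry per (compound, reagent ion) reaction. Fields:
#   compound    name; a pipe-separated name ("a|b") is an unresolved candidate
#               set that shares one product-ion channel and is never split
#   molar_mass  g/mol of the neutral analyte (candidate sets: mean of members,
#               which agree to <0.1%)
#   reagent     H3O+, NO+ or O2+
#   k           ion-molecule rate coefficient, cm^3 s^-1. These are
#               literature-scale defaults, NOT instrument-calibrated values;
#               edit freely. They set the absolute concentration scale only.
#   channels    product-ion channels:
#     base_mz     integer nominal m/z of the all-35Cl, unhydrated product ion
#     branching   fraction of reaction flux (sums to 1 within an entry)
#     n_chlorine  chlorine atoms retained in the product ion
#     hydrates    whether the ion forms an (H2O)_0..3 cluster series under
#                 humid hydronium chemistry
version: 1
compounds:
  - compound: ammonia
    molar_mass: 17.03
    reagent: H3O+
    k: 2.6e-9
    channels:
      - {base_mz: 18, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: ammonia
    molar_mass: 17.03
    reagent: O2+
    k: 2.4e-9
    channels:
      - {base_mz: 17, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: acetaldehyde
    molar_mass: 44.05
    reagent: H3O+
    k: 3.7e-9
    channels:
      - {base_mz: 45, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: acetone
    molar_mass: 58.08
    reagent: H3O+
    k: 3.9e-9
    channels:
      - {base_mz: 59, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: methanol
    molar_mass: 32.04
    reagent: H3O+
    k: 2.7e-9
    channels:
      - {base_mz: 33, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: ethanol
    molar_mass: 46.07
    reagent: H3O+
    k: 2.7e-9
    channels:
      - {base_mz: 47, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: acetic_acid
    molar_mass: 60.05
    reagent: NO+
    k: 2.5e-9
    channels:
      - {base_mz: 90, branching: 1.0, n_chlorine: 0, hydrates: false}
  - compound: acetonitrile
    molar_mass: 41.05
    reagent: H3O+
    k: 5.1e-9
    channels:
      - {base_mz: 42, branching: 1.0, n_chlorine: 0, hydrates: true}
  - compound: chloroform
    molar_mass: 119.38
    reagent: O2+
    k: 1.5e-9
    channels:
      - {base_mz: 83, branching: 1.0, n_chlorine: 2, hydrates: false}
  - compound: pentylamine|butyramide
    molar_mass: 87.14
    reagent: H3O+
    k: 2.5e-9
    channels:
      - {base_mz: 88, branching: 1.0, n_chlorine: 0, hydrates: true}
  - compound: dipropylamine|pentanamide
    molar_mass: 101.17
    reagent: H3O+
    k: 2.5e-9
    channels:
      - {base_mz: 102, branching: 1.0, n_chlorine: 0, hydrates: true}
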