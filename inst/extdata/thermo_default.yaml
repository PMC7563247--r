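# Default thermodynamic constant set for sulfate/chloride-rich acidic waters.
# Formation constants are 25 degC, I = 0, association convention on activities,
# taken from standard geochemical compilations (MINTEQ-family values). They are
# generic reference values, editable by the user, and carry no site-specific
# calibration.
components:
  Al: 3
  Fe(II): 2
  Fe(III): 3
  Cu: 2
  Zn: 2
  Mn: 2
  Ni: 2
  Co: 2
  Cd: 2
  SO4: -2
  Cl: -1
  As(III): 0
  As(V): 0
complexes:
  - name: HSO4-
    stoichiometry: {SO4: 1, H: 1}
    log10_K: 1.99
    charge: -1
  - name: AlSO4+
    stoichiometry: {Al: 1, SO4: 1}
    log10_K: 3.50
    charge: 1
  - name: Al(SO4)2-
    stoichiometry: {Al: 1, SO4: 2}
    log10_K: 5.00
    charge: -1
  - name: FeSO4
    stoichiometry: {Fe(II): 1, SO4: 1}
    log10_K: 2.25
    charge: 0
  - name: FeCl+
    stoichiometry: {Fe(II): 1, Cl: 1}
    log10_K: 0.14
    charge: 1
  - name: FeSO4+
    stoichiometry: {Fe(III): 1, SO4: 1}
    log10_K: 4.04
    charge: 1
  - name: Fe(SO4)2-
    stoichiometry: {Fe(III): 1, SO4: 2}
    log10_K: 5.38
    charge: -1
  - name: FeCl2+
    stoichiometry: {Fe(III): 1, Cl: 1}
    log10_K: 1.48
    charge: 2
  - name: CuSO4
    stoichiometry: {Cu: 1, SO4: 1}
    log10_K: 2.36
    charge: 0
  - name: CuCl+
    stoichiometry: {Cu: 1, Cl: 1}
    log10_K: 0.43
    charge: 1
  - name: ZnSO4
    stoichiometry: {Zn: 1, SO4: 1}
    log10_K: 2.37
    charge: 0
  - name: Zn(SO4)2-2
    stoichiometry: {Zn: 1, SO4: 2}
    log10_K: 3.28
    charge: -2
  - name: ZnCl+
    stoichiometry: {Zn: 1, Cl: 1}
    log10_K: 0.45
    charge: 1
  - name: MnSO4
    stoichiometry: {Mn: 1, SO4: 1}
    log10_K: 2.26
    charge: 0
  - name: MnCl+
    stoichiometry: {Mn: 1, Cl: 1}
    log10_K: 0.61
    charge: 1
  - name: NiSO4
    stoichiometry: {Ni: 1, SO4: 1}
    log10_K: 2.32
    charge: 0
  - name: CoSO4
    stoichiometry: {Co: 1, SO4: 1}
    log10_K: 2.30
    charge: 0
  - name: CoCl+
    stoichiometry: {Co: 1, Cl: 1}
    log10_K: 0.57
    charge: 1
  - name: H2AsO3-
    stoichiometry: {As(III): 1, H: -1}
    log10_K: -9.22
    charge: -1
  - name: H2AsO4-
    stoichiometry: {As(V): 1, H: -1}
    log10_K: -2.24
    charge: -1
  - name: HAsO4-2
    stoichiometry: {As(V): 1, H: -2}
    log10_K: -9.20
    charge: -2
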