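<!-- Document type definition for isomer enumeration results -->
<!ELEMENT isomer_enumeration (formula_isomers*)>
<!ATTLIST isomer_enumeration formula CDATA #REQUIRED>
<!ELEMENT formula_isomers (constitutional_isomer*)>
<!ATTLIST formula_isomers
  formula          CDATA #REQUIRED
  n_constitutional CDATA #REQUIRED
  n_spatial        CDATA #IMPLIED>
<!ELEMENT constitutional_isomer (stereoisomer*)>
<!ATTLIST constitutional_isomer
  id     ID    #REQUIRED
  smiles CDATA #REQUIRED>
<!ELEMENT stereoisomer EMPTY>
<!ATTLIST stereoisomer
  id         ID    #REQUIRED
  smiles     CDATA #REQUIRED
  n_tet      CDATA #REQUIRED
  n_ct       CDATA #REQUIRED
  enantiomer IDREF #IMPLIED>
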