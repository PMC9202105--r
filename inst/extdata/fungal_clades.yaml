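# Default seven-node fungal clade ladder (root-to-tip order). The
# Blastocladiomycota/Chytridiomycota branching is treated as an unresolved
# pair inside the second node. Terminal phyla are evaluated per subphylum.
nodes:
  - name: MRCA_Fungi
    phyla: [Cryptomycota, Chytridiomycota, Blastocladiomycota,
            Zoopagomycota, Mucoromycota, Ascomycota, Basidiomycota]
  - name: MRCA_Blastocladiomycota_sisters
    phyla: [Chytridiomycota, Blastocladiomycota, Zoopagomycota,
            Mucoromycota, Ascomycota, Basidiomycota]
  - name: MRCA_Zoopagomycota_sisters
    phyla: [Zoopagomycota, Mucoromycota, Ascomycota, Basidiomycota]
  - name: MRCA_Mucoromycota_sisters
    phyla: [Mucoromycota, Ascomycota, Basidiomycota]
  - name: Dikarya
    phyla: [Ascomycota, Basidiomycota]
  - name: Ascomycota
    phyla: [Ascomycota]
    terminal: true
  - name: Basidiomycota
    phyla: [Basidiomycota]
    terminal: true
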