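min_domain_len: 100.0
zn_len_threshold: 140.0
profiles:
- name: HsGLYI_like
  metal_type: Zn
  synthetic: yes
  domain_sequence: IIMRSLCMLTPYTRHGWELMISQCNWYGGHTIMQGIGRTIQRPQISCDNEMPEHCMIGDECPAVQMVHHPGCWLYWCQNSKRCSHVISPHDECDFKAAKEHRPNFGWTSSMKCNGECADLEVIFTKHRPVPKVLEYDIGTWAVKEQDYRNVDPDYHADHNMNHHNVGHKGVHEPHRDNHQTAQQ
  sites:
  - site: metal1
    role: metal
    ref_pos: 34
    expected: Q
  - site: gsh1
    role: gsh
    ref_pos: 38
    expected: R
  - site: metal2
    role: metal
    ref_pos: 100
    expected: E
  - site: gsh2
    role: gsh
    ref_pos: 104
    expected: 'N'
  - site: dimer
    role: dimer
    ref_pos: 106
    expected: G
  - site: metal3
    role: metal
    ref_pos: 127
    expected: H
  - site: metal4
    role: metal
    ref_pos: 173
    expected: E
- name: EcGLYI_like
  metal_type: Ni
  synthetic: yes
  domain_sequence: HTIMHGIGRHCMIGDECPAVQMVHHPGCWLYWCQNSKRCSHVISPHDECDFKAAKEHRPNFGECADLEVIFTKHGSRPVPKVLEYDIGTWAVKEQDYRNVDPDYHADHNMNHHNVGHKGVHEPHRDNHQTAQQ
  sites:
  - site: metal1
    role: metal
    ref_pos: 5
    expected: H
  - site: gsh1
    role: gsh
    ref_pos: 9
    expected: R
  - site: metal2
    role: metal
    ref_pos: 56
    expected: E
  - site: gsh2
    role: gsh
    ref_pos: 60
    expected: 'N'
  - site: dimer
    role: dimer
    ref_pos: 62
    expected: G
  - site: metal3
    role: metal
    ref_pos: 74
    expected: H
  - site: metal4
    role: metal
    ref_pos: 122
    expected: E
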