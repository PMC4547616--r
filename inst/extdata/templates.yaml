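- key: PC
  category: Glycerophospholipid
  class_name: Glycerophosphocholine
  subclass_name: Diacylglycerophosphocholine
  abbreviation: PC
  backbone: C({1})[C@@H]({2})COP(=O)([O-])OCC[N+](C)(C)C
  backbone_name: sn-glycero-3-phosphocholine
  slots:
  - sn: 1
    linkages:
    - ester
    may_be_empty: no
  - sn: 2
    linkages:
    - ester
    may_be_empty: no
- key: PC-O
  category: Glycerophospholipid
  class_name: Glycerophosphocholine
  subclass_name: Monoalkylmonoacylglycerophosphocholine
  abbreviation: PC
  backbone: C({1})[C@@H]({2})COP(=O)([O-])OCC[N+](C)(C)C
  backbone_name: sn-glycero-3-phosphocholine
  slots:
  - sn: 1
    linkages:
    - alkyl
    - alkenyl
    may_be_empty: no
  - sn: 2
    linkages:
    - ester
    may_be_empty: no
- key: LPC
  category: Glycerophospholipid
  class_name: Glycerophosphocholine
  subclass_name: Monoacylglycerophosphocholine
  abbreviation: LPC
  backbone: C({1})[C@@H]({2})COP(=O)([O-])OCC[N+](C)(C)C
  backbone_name: sn-glycero-3-phosphocholine
  slots:
  - sn: 1
    linkages:
    - ester
    may_be_empty: no
  - sn: 2
    linkages: []
    may_be_empty: yes
- key: TG
  category: Glycerolipid
  class_name: Triradylglycerol
  subclass_name: Triacylglycerol
  abbreviation: TG
  backbone: C({1})[C@@H]({2})C({3})
  backbone_name: sn-glycerol
  slots:
  - sn: 1
    linkages:
    - ester
    may_be_empty: no
  - sn: 2
    linkages:
    - ester
    may_be_empty: no
  - sn: 3
    linkages:
    - ester
    may_be_empty: no
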