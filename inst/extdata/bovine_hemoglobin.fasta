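>alpha Bovine hemoglobin subunit alpha, mature chain (141 aa)
VLSAADKGNVKAAWGKVGGHAAEYGAEALERMFLSFPTTKTYFPHFDLSHGSAQVKGHGA
KVAAALTKAVEHLDDLPGALSELSDLHAHKLRVDPVNFKLLSHSLLVTLASHLPSDFTPA
VHASLDKFLANVSTVLTSKYR
>beta Bovine hemoglobin subunit beta, mature chain (145 aa)
MLTAEEKAAVTAFWGKVKVDEVGGEALGRLLVVYPWTQRFFESFGDLSTADAVMNNPKVK
AHGKKVLDSFSNGMKHLDDLKGTFAALSELHCDKLHVDPENFKLLGNVLVVVLARNFGKE
FTPVLQADFQKVVAGVANALAHRYH
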