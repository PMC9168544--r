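>LPR1_like_synthetic
DPKIPRKCNILQISVFGDKSISVVIGLPHNGESTMPNVATANMSCKTIKKYQMYIVDVPV
MCYCVIFTSKRMIMPNCYAPELHNPHWELTGNQMKIAMLVNDRFVCAMHCAGQIRRCRME
DCDVIPVSGIRYMKKHPEIDQNQFPDWMRTAWPMGLHSGCQHDVLVNRFEQIYTSQCYDD
DCEIRVIQCSTTDQTFGQQLYLLADKRADFHMLDRAKWVLSHLWAKHETGEFEVSRKCYH
AASYCKLTYMKTTINEPLWCDLARMVWPEFCGSLECAVPYPPLQPEMMNWPHYMREKLHA
LTWCRDQEINIFHGRSWSKHKVQWKYHCYYENETLESNRNQDLPAHIAPLFVGYTEMLCN
TGDIPYPNGDRGSEMGIMCFASACHDFAVAWQGECNNQSESTLMASVCPTQTKHRCDFES
CPQMFYEGYFYMTQQARKPQAALGPAIIGFGVITKYWNMTTDQHPLNTMEECMSLRLEGV
WYWNDDVMGPRDKKQPPVPYGNRIVMGEHWCDDIHVMTEDYWDWCRFPCGYSSEYIHGLT
EHVQLMGVVTAWWNPLNWMNCKLESREMAVAMTPVIFWNC
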