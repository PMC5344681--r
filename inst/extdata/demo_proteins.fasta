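>H3_TAIL synthetic demo: histone H3 N-terminal region
MARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALR
>PARP1_AMD synthetic demo: automodification-region fragment
MSEVKAAPRGKSGAALSKKSKGQVKEEGINKSEKRMKGGALK
>DEC1 synthetic decoy protein
MLEVNKAGSTLDKRFAEQWVNPLGHYKTSVDKAAGIR
>DEC2 synthetic decoy protein
MTQAGLFDKSVERPLNGAYWKHSDEIKVTGMNPR
>DEC3 synthetic decoy protein
MGWAETKLNSDVKQPFHYRAGSLEIKTVNDR
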