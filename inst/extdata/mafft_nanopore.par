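# MAFFT parameters for indel-rich nanopore reads.
# One key=value (or bare flag) per line; keys become --key arguments.
op=0
ep=1
retree=2
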