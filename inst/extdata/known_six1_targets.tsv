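gene_id	source
Atoh1	prior Six1 target study
Slc12a2	prior Six1 target study
CyclinA1	prior Six1 target study
CyclinD1	prior Six1 target study
c-Myc	prior Six1 target study
Ezrin	prior Six1 target study
Gdnf	prior Six1 target study
Sox3	prior Six1 target study
Sox2	prior Six1 target study
Sall1	prior Six1 target study
MyoD1	prior Six1 target study
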