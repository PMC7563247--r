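layer	tpf_type	ranking
upper	tpf1	Al > Cu > Fe(III) ~ Mn ~ Zn ~ Co > Ni > As(V)
chemocline	tpf1	Al > Fe(II) > Zn > Mn > Co > Ni > Cu > As(V)
deep	tpf1	Fe(II) >> Zn > Mn > As(III) ~ Co > Al > Ni > Cu
upper	tpf2	Cu > Al > Mn > Co > Zn > Fe(III) ~ Ni
chemocline	tpf2	Fe(II) > Al > Mn > Zn > Co > Ni > Cu
deep	tpf2	Fe(II) >> Mn > Zn > Co > Ni > Al > Cu
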