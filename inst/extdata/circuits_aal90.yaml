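DMN:
- SFGmed.L
- SFGmed.R
- ORBsupmed.L
- ORBsupmed.R
- PCG.L
- PCG.R
- ANG.L
- ANG.R
SC:
- ACG.L
- ACG.R
- INS.L
- INS.R
- AMYG.L
- AMYG.R
NAC:
- AMYG.L
- AMYG.R
- HIP.L
- HIP.R
- INS.L
- INS.R
- MFG.L
- MFG.R
- ORBinf.L
- ORBinf.R
- ORBmid.L
- ORBmid.R
PAC:
- CAU.L
- CAU.R
- PUT.L
- PUT.R
- PAL.L
- PAL.R
- ORBsup.L
- ORBsup.R
- ORBmid.L
- ORBmid.R
- ORBinf.L
- ORBinf.R
- ORBsupmed.L
- ORBsupmed.R
- REC.L
- REC.R
- SFGmed.L
- SFGmed.R
AC:
- SFGmed.L
- SFGmed.R
- INS.L
- INS.R
- IPL.L
- IPL.R
- PCUN.L
- PCUN.R
CCC:
- MFG.L
- MFG.R
- SFGdor.L
- SFGdor.R
- ACG.L
- ACG.R
- SPG.L
- SPG.R
- IPL.L
- IPL.R
- PreCG.L
- PreCG.R
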