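node_id	label	hemisphere	homologue_id
PreCG.L	Precentral gyrus left	left	PreCG.R
PreCG.R	Precentral gyrus right	right	PreCG.L
SFGdor.L	Superior frontal gyrus (dorsolateral) left	left	SFGdor.R
SFGdor.R	Superior frontal gyrus (dorsolateral) right	right	SFGdor.L
ORBsup.L	Superior frontal gyrus (orbital) left	left	ORBsup.R
ORBsup.R	Superior frontal gyrus (orbital) right	right	ORBsup.L
MFG.L	Middle frontal gyrus left	left	MFG.R
MFG.R	Middle frontal gyrus right	right	MFG.L
ORBmid.L	Middle frontal gyrus (orbital) left	left	ORBmid.R
ORBmid.R	Middle frontal gyrus (orbital) right	right	ORBmid.L
IFGoperc.L	Inferior frontal gyrus (opercular) left	left	IFGoperc.R
IFGoperc.R	Inferior frontal gyrus (opercular) right	right	IFGoperc.L
IFGtriang.L	Inferior frontal gyrus (triangular) left	left	IFGtriang.R
IFGtriang.R	Inferior frontal gyrus (triangular) right	right	IFGtriang.L
ORBinf.L	Inferior frontal gyrus (orbital) left	left	ORBinf.R
ORBinf.R	Inferior frontal gyrus (orbital) right	right	ORBinf.L
ROL.L	Rolandic operculum left	left	ROL.R
ROL.R	Rolandic operculum right	right	ROL.L
SMA.L	Supplementary motor area left	left	SMA.R
SMA.R	Supplementary motor area right	right	SMA.L
OLF.L	Olfactory cortex left	left	OLF.R
OLF.R	Olfactory cortex right	right	OLF.L
SFGmed.L	Superior frontal gyrus (medial) left	left	SFGmed.R
SFGmed.R	Superior frontal gyrus (medial) right	right	SFGmed.L
ORBsupmed.L	Superior frontal gyrus (medial orbital) left	left	ORBsupmed.R
ORBsupmed.R	Superior frontal gyrus (medial orbital) right	right	ORBsupmed.L
REC.L	Gyrus rectus left	left	REC.R
REC.R	Gyrus rectus right	right	REC.L
INS.L	Insula left	left	INS.R
INS.R	Insula right	right	INS.L
ACG.L	Anterior cingulate and paracingulate gyri left	left	ACG.R
ACG.R	Anterior cingulate and paracingulate gyri right	right	ACG.L
DCG.L	Median cingulate and paracingulate gyri left	left	DCG.R
DCG.R	Median cingulate and paracingulate gyri right	right	DCG.L
PCG.L	Posterior cingulate gyrus left	left	PCG.R
PCG.R	Posterior cingulate gyrus right	right	PCG.L
HIP.L	Hippocampus left	left	HIP.R
HIP.R	Hippocampus right	right	HIP.L
PHG.L	Parahippocampal gyrus left	left	PHG.R
PHG.R	Parahippocampal gyrus right	right	PHG.L
AMYG.L	Amygdala left	left	AMYG.R
AMYG.R	Amygdala right	right	AMYG.L
CAL.L	Calcarine fissure left	left	CAL.R
CAL.R	Calcarine fissure right	right	CAL.L
CUN.L	Cuneus left	left	CUN.R
CUN.R	Cuneus right	right	CUN.L
LING.L	Lingual gyrus left	left	LING.R
LING.R	Lingual gyrus right	right	LING.L
SOG.L	Superior occipital gyrus left	left	SOG.R
SOG.R	Superior occipital gyrus right	right	SOG.L
MOG.L	Middle occipital gyrus left	left	MOG.R
MOG.R	Middle occipital gyrus right	right	MOG.L
IOG.L	Inferior occipital gyrus left	left	IOG.R
IOG.R	Inferior occipital gyrus right	right	IOG.L
FFG.L	Fusiform gyrus left	left	FFG.R
FFG.R	Fusiform gyrus right	right	FFG.L
PoCG.L	Postcentral gyrus left	left	PoCG.R
PoCG.R	Postcentral gyrus right	right	PoCG.L
SPG.L	Superior parietal gyrus left	left	SPG.R
SPG.R	Superior parietal gyrus right	right	SPG.L
IPL.L	Inferior parietal lobule left	left	IPL.R
IPL.R	Inferior parietal lobule right	right	IPL.L
SMG.L	Supramarginal gyrus left	left	SMG.R
SMG.R	Supramarginal gyrus right	right	SMG.L
ANG.L	Angular gyrus left	left	ANG.R
ANG.R	Angular gyrus right	right	ANG.L
PCUN.L	Precuneus left	left	PCUN.R
PCUN.R	Precuneus right	right	PCUN.L
PCL.L	Paracentral lobule left	left	PCL.R
PCL.R	Paracentral lobule right	right	PCL.L
CAU.L	Caudate nucleus left	left	CAU.R
CAU.R	Caudate nucleus right	right	CAU.L
PUT.L	Putamen left	left	PUT.R
PUT.R	Putamen right	right	PUT.L
PAL.L	Pallidum left	left	PAL.R
PAL.R	Pallidum right	right	PAL.L
THA.L	Thalamus left	left	THA.R
THA.R	Thalamus right	right	THA.L
HES.L	Heschl gyrus left	left	HES.R
HES.R	Heschl gyrus right	right	HES.L
STG.L	Superior temporal gyrus left	left	STG.R
STG.R	Superior temporal gyrus right	right	STG.L
TPOsup.L	Temporal pole (superior) left	left	TPOsup.R
TPOsup.R	Temporal pole (superior) right	right	TPOsup.L
MTG.L	Middle temporal gyrus left	left	MTG.R
MTG.R	Middle temporal gyrus right	right	MTG.L
TPOmid.L	Temporal pole (middle) left	left	TPOmid.R
TPOmid.R	Temporal pole (middle) right	right	TPOmid.L
ITG.L	Inferior temporal gyrus left	left	ITG.R
ITG.R	Inferior temporal gyrus right	right	ITG.L
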