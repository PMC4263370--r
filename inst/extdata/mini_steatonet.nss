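# Reduced liver-adipose-blood metabolic network with hormonal and
# transcriptional regulation. Glucose influx -> glycolysis -> acetyl-CoA ->
# lipogenesis (ACC1, FAS, SCD1, GPAT) -> triglycerides -> VLDL; beta-oxidation
# (CPT1); glycogen; gluconeogenesis (PEPCK); ketone bodies; cholesterol and
# lipoproteins; adipose storage/lipolysis; insulin/glucagon/PPARa switches;
# SREBP-1c, adiponectin and TNFa regulation.

@compartments
liver adipose blood pancreas peripheral

@metabolites
glc_B blood
fa_B blood
tg_B blood
kb_B blood
vldl_B blood
ldl_B blood
hdl_B blood
glc_L liver
g6p_L liver
glycogen_L liver
pyr_L liver
acoa_L liver
malonyl_L liver
fa_sat_L liver
fa_L liver
tg_L liver
kb_L liver
chol_L liver
ceramide_L liver
bile_L liver
co2_L liver
glc_A adipose
fa_A adipose
tg_A adipose
acoa_A adipose
glc_P peripheral
chol_P peripheral

@enzymes
GK liver
PFK liver
GS liver
G6Pase liver
GP liver
PDH liver
PEPCK liver gene=pepck_g
ACC1 liver gene=acc1_g
FAS liver gene=fas_g
SCD1 liver gene=scd_g
CPT1 liver gene=cpt1_g
GPAT liver gene=gpat_g
SPT liver
CDase liver gene=cdase_g
HMGCS liver gene=hmgs_g
HMGCR liver
CS liver
MTP liver
ATGL liver gene=atgl_g
CYP7A1 liver gene=cyp7_g
LPL blood
LDLR liver
FATP_L liver gene=fatp_l_g
FATP_A adipose gene=fatp_a_g
DGAT adipose
CPT1A adipose gene=cpt1a_g
HSL adipose gene=hsl_g
GLYA adipose

@reactions
t_glc_L: glc_B -> glc_L | r=0.5
t_glc_A: glc_B -> glc_A | r=0
t_glc_P: glc_B -> glc_P | r=0
t_glc_rel: glc_L -> glc_B | r=0
gk: glc_L -> g6p_L | enzyme=GK r=0
pfk: g6p_L -> pyr_L | enzyme=PFK r=0
gsyn: g6p_L -> glycogen_L | enzyme=GS r=0
g6pase: g6p_L -> glc_L | enzyme=G6Pase r=0
glyphos: glycogen_L -> g6p_L | enzyme=GP r=0
pdh: pyr_L -> acoa_L | enzyme=PDH r=0
pepck: pyr_L -> g6p_L | enzyme=PEPCK r=0
acc: acoa_L -> malonyl_L | enzyme=ACC1 r=0
fas: malonyl_L -> fa_sat_L | enzyme=FAS r=0
scd: fa_sat_L -> fa_L | enzyme=SCD1 r=0
box_s: fa_sat_L -> acoa_L | enzyme=CPT1 r=0
gpat: fa_L -> tg_L | enzyme=GPAT r=0
cersyn: fa_L -> ceramide_L | enzyme=SPT r=0
cerase: ceramide_L -> co2_L | enzyme=CDase r=0
hmgs: acoa_L -> kb_L | enzyme=HMGCS r=0
chsyn: acoa_L -> chol_L | enzyme=HMGCR r=0
tca: acoa_L -> co2_L | enzyme=CS r=0
vldl_sec: tg_L -> vldl_B | enzyme=MTP r=0
lipo_L: tg_L -> fa_sat_L | enzyme=ATGL r=0
bilesyn: chol_L -> bile_L | enzyme=CYP7A1 r=0
chol_vldl: chol_L -> vldl_B | r=0
vldl_lpl: vldl_B -> fa_B | enzyme=LPL r=0
vldl_ldl: vldl_B -> ldl_B | r=0
ldl_up_L: ldl_B -> chol_L | enzyme=LDLR r=0
ldl_up_P: ldl_B -> chol_P | r=0
hdl_rct: hdl_B -> chol_L | r=0
cm_lpl: tg_B -> fa_B | enzyme=LPL r=0
t_tg_L: tg_B -> tg_L | r=0
t_kb: kb_L -> kb_B | r=0.2
t_kb_A: kb_B -> acoa_A | r=0
t_fa_L: fa_B -> fa_sat_L | enzyme=FATP_L r=0
t_fa_A: fa_B -> fa_A | enzyme=FATP_A r=0
est_A: fa_A -> tg_A | enzyme=DGAT r=0
box_A: fa_A -> acoa_A | enzyme=CPT1A r=0
lip_A: tg_A -> fa_B | enzyme=HSL r=0
gly_A: glc_A -> acoa_A | enzyme=GLYA r=0

@branches
glc_B: t_glc_L=0.5 t_glc_A=0.2 t_glc_P=0.3
glc_L: gk=0.8 t_glc_rel=0.2
g6p_L: pfk=0.55 gsyn=0.2 g6pase=0.25
pyr_L: pdh=0.75 pepck=0.25
acoa_L: acc=0.3 hmgs=0.15 chsyn=0.1 tca=0.45
fa_sat_L: scd=0.6 box_s=0.4
fa_L: gpat=0.75 cersyn=0.25
tg_L: vldl_sec=0.65 lipo_L=0.35
kb_B: t_kb_A=0.4 sink=0.6
chol_L: bilesyn=0.5 chol_vldl=0.5
vldl_B: vldl_lpl=0.6 vldl_ldl=0.4
ldl_B: ldl_up_L=0.6 ldl_up_P=0.4
tg_B: cm_lpl=0.75 t_tg_L=0.25
fa_B: t_fa_L=0.4 t_fa_A=0.35 sink=0.25
fa_A: est_A=0.6 box_A=0.4

@sources
glc_B 1.0
tg_B 0.5
chol_L 0.2
hdl_B 0.1

@genes
pepck_g enzyme=PEPCK
acc1_g enzyme=ACC1
fas_g enzyme=FAS
scd_g enzyme=SCD1
cpt1_g enzyme=CPT1
gpat_g enzyme=GPAT
cdase_g enzyme=CDase
cyp7_g enzyme=CYP7A1
fatp_l_g enzyme=FATP_L
fatp_a_g enzyme=FATP_A
cpt1a_g enzyme=CPT1A
hsl_g enzyme=HSL
hmgs_g enzyme=HMGCS
atgl_g enzyme=ATGL
srebp1c_g protein=SREBP1c
tnfa_g protein=TNFA
adipo_g protein=adipo

@tf
ins_a -> srebp1c_g + Qmax=6 Qhat=2 hill=4 basal=0.05
adipo -> srebp1c_g - Qmax=4 hill=2
SREBP1c -> acc1_g + Qmax=6 Qhat=6 hill=2 basal=0.05
SREBP1c -> fas_g + Qmax=6 Qhat=6 hill=2 basal=0.05
SREBP1c -> scd_g + Qmax=4 Qhat=6 hill=2 basal=0.4
SREBP1c -> gpat_g + Qmax=2.5 Qhat=6 hill=2 basal=0.2
gcg_a -> pepck_g + Qmax=4 Qhat=2 hill=4 basal=0.1
ins_a -> pepck_g - Qmax=4 hill=2
ppara_a -> cpt1_g + Qmax=4 Qhat=2 hill=4 basal=0.5
gcg_a -> cpt1_g + Qmax=4 Qhat=2 hill=6 basal=0.85
adipo -> cpt1_g + Qmax=1.85 Qhat=8 hill=2 basal=0.5
gcg_a -> hmgs_g + Qmax=4 Qhat=2 hill=6 basal=0.85
ppara_a -> atgl_g + Qmax=6 Qhat=2 hill=4 basal=0.5
ppara_a -> cyp7_g + Qmax=4 Qhat=2 hill=4 basal=0.3
gcg_a -> hsl_g + Qmax=3 Qhat=2 hill=4 basal=0.2
ins_a -> hsl_g - Qmax=3 hill=2
ins_a -> fatp_l_g + Qmax=3 Qhat=2 hill=4 basal=0.3
adipo -> fatp_l_g + Qmax=2.5 Qhat=8 hill=2 basal=0.4
ins_a -> fatp_a_g + Qmax=2 Qhat=2 hill=4 basal=0.3
adipo -> fatp_a_g + Qmax=4 Qhat=8 hill=2 basal=0.3
adipo -> cpt1a_g + Qmax=6 Qhat=8 hill=2 basal=0.3
adipo -> cdase_g + Qmax=6 Qhat=8 hill=2 basal=0.3
adipo -> tnfa_g - Qmax=6 hill=2

@switches
ins: act=glc_B ka=0.02 kd=0.01
gcg: inh=glc_B ka=0.1 kd=0.01
ppara: act=fa_sat_L ka=0.02 kd=0.01
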