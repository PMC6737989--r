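gene_id	mirna_id	r
MYOD1	novel_6_20992	-0.5390881
HBEGF	novel_6_20992	-0.7102848
ACHE	novel_X_29788	-0.7475892
SRF	novel_X_29788	-0.9981668
CALR	novel_15_11149	-0.7613538
GYLTL1B	novel_15_11149	-0.8369125
METTL21A	novel_15_11149	-0.8442253
WASL	novel_15_11149	-0.8928107
WASF3	novel_15_11149	-0.8967293
RASA1	novel_15_11149	-0.9028681
CSRP2	novel_15_11149	-0.9587139
EZR	novel_15_11149	-0.9827896
PPP3CB	novel_4_18615	-0.6112719
MBNL1	novel_4_18615	-0.7985375
FHOD1	novel_12_5322	-0.6604956
ACADM	novel_12_5365	-0.9987412
MET	novel_GL896243.1_30542	-0.6683036
SOD1	novel_GL896243.1_30542	-0.9586679
RCAN1	novel_12_5576	-0.9999364
SGCA	novel_1_1367	-0.9808128
SRF	novel_1_1367	-0.8138354
SIRT2	novel_X_29783	-0.8866714
RXRG	ssc-miR-296-3p	-0.9848669
NOS1	ssc-miR-296-3p	-0.963125
MYL1	ssc-miR-497	-0.7053538
ACTA1	ssc-miR-1307	-0.7243173
MTSS1	novel_9_27936	-0.5860598
SMARCD3	novel_10_2856	-0.5633121
RHOQ	novel_10_2856	-0.8857205
CAPZA2	novel_4_17324	-0.9810114
LIMK1	novel_9_27762	-0.9571368
FHOD1	novel_9_27796	-0.6414053
MEF2A	novel_6_22335	-0.8056134
MTM1	novel_2_14454	-0.6334166
MTM1	novel_2_15515	-0.9702249
GPHN	novel_15_11290	-0.7468672
LBX1	novel_16_11622	-0.9452654
MEF2D	novel_13_6599	-0.9327755
IGFBP5	novel_4_18039	-0.9461923
PDGFA	novel_13_7087	-0.9090636
PDGFA	novel_5_19528	-0.8911486
AMOT	novel_3_15819	-0.577509
SPTAN1	novel_2_15576	-0.8980043
MTSS1	novel_12_5119	-0.7397887
PDPK1	novel_17_12538	-0.9859897
WIPF1	novel_14_8940	-0.8267719
CDC42BPB	novel_17_12654	-0.9731097
SIX4	ssc-miR-744	-0.8646932
PROX1	ssc-miR-338	-0.9395592
QKI	ssc-miR-423-3p	-0.9453357
ACTN4	ssc-miR-133a-3p	-0.6850723
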