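entry_id,abbreviation,name,formula,polarity,derivatization,n_obha_sites,q1,q3_list,ce_list,fragment_list,rt,method_tag,gradient,anomaly,comment
K.pos,K,Lysine,C6H14N2O2,positive,none,0,147.0,84.1,16,loss:CH5NO2,2.72,pos_underivatized,positive_underivatized,,Q1/Q3 shared with glutamine; resolved by RT
H.pos,H,Histidine,C6H9N3O2,positive,none,0,156.0,110.0,12,loss:CH2O2,2.76,pos_underivatized,positive_underivatized,,
R.pos,R,Arginine,C6H14N4O2,positive,none,0,175.2,60.0,14,none,2.79,pos_underivatized,positive_underivatized,,
S.pos,S,Serine,C3H7NO3,positive,none,0,106.0,60.0,13,loss:CH2O2,3.27,pos_underivatized,positive_underivatized,,
A.pos,A,Alanine,C3H7NO2,positive,none,0,90.0,44.0,11,loss:CH2O2,3.30,pos_underivatized,positive_underivatized,,
N.pos,N,Asparagine,C4H8N2O3,positive,none,0,133.1,74.0,15,none,3.30,pos_underivatized,positive_underivatized,,
Q.pos,Q,Glutamine,C5H10N2O3,positive,none,0,147.0,84.1,16,loss:CH5NO2,3.36,pos_underivatized,positive_underivatized,,Q1/Q3 shared with lysine; resolved by RT
T.pos,T,Threonine,C4H9NO3,positive,none,0,120.0,56.0,30,none,3.39,pos_underivatized,positive_underivatized,,
D.pos,D,Aspartate,C4H7NO4,positive,none,0,134.1,74.0,15,loss:C2H4O2,3.46,pos_underivatized,positive_underivatized,,
E.pos,E,Glutamate,C5H9NO4,positive,none,0,148.1,84.1,16,loss:CH4O3,3.48,pos_underivatized,positive_underivatized,,
C.pos,C,Cysteine,C3H7NO2S,positive,none,0,122.2,59.0,27,loss:CH5NO2,3.58,pos_underivatized,positive_underivatized,,
P.pos,P,Proline,C5H9NO2,positive,none,0,116.0,70.0,11,loss:CH2O2,3.84,pos_underivatized,positive_underivatized,,
V.pos,V,Valine,C5H11NO2,positive,none,0,118.0,72.0,15,loss:CH2O2,4.35,pos_underivatized,positive_underivatized,,
M.pos,M,Methionine,C5H11NO2S,positive,none,0,150.1,56.0,15,none,5.30,pos_underivatized,positive_underivatized,,
I.pos,I,Isoleucine,C6H13NO2,positive,none,0,132.0,86.0,11,loss:CH2O2,6.53,pos_underivatized,positive_underivatized,,Q1/Q3 shared with leucine; resolved by RT
L.pos,L,Leucine,C6H13NO2,positive,none,0,132.0,86.0,11,loss:CH2O2,6.90,pos_underivatized,positive_underivatized,,Q1/Q3 shared with isoleucine; resolved by RT
Y.pos,Y,Tyrosine,C9H11NO3,positive,none,0,182.2,136.0,14,loss:CH2O2,7.04,pos_underivatized,positive_underivatized,,
F.pos,F,Phenylalanine,C9H11NO2,positive,none,0,166.0,120.0,25,loss:CH2O2,9.12,pos_underivatized,positive_underivatized,,
W.pos,W,Tryptophan,C11H12N2O2,positive,none,0,205.0,146.0,16,none,10.14,pos_underivatized,positive_underivatized,,
AMP.pos,AMP,Adenosine 5'-monophosphate,C10H14N5O7P,positive,none,0,348,136,21,product:C5H5N5,6.62,pos_underivatized,positive_underivatized,,Release of nitrogen base monitored
GMP.pos,GMP,Guanosine 5'-monophosphate,C10H14N5O8P,positive,none,0,364,152,18,product:C5H5N5O,7.96,pos_underivatized,positive_underivatized,,Release of nitrogen base monitored
CMP.pos,CMP,Cytidine 5'-monophosphate,C9H14N3O8P,positive,none,0,324,112,21,product:C4H5N3O,4.57,pos_underivatized,positive_underivatized,,Release of nitrogen base monitored
UMP.pos,UMP,Uridine 5'-monophosphate,C9H13N2O9P,positive,none,0,325,113,21,product:C4H4N2O2,7.83,pos_underivatized,positive_underivatized,,Release of nitrogen base monitored
SAM.pos,SAM,S-Adenosyl methionine,C15H22N6O5S,positive,none,0,399,250,13,none,2.86,pos_underivatized,positive_underivatized,,
SAH.pos,SAH,S-Adenosyl homocysteine,C14H20N6O5S,positive,none,0,385,136,19,product:C5H5N5,6.92,pos_underivatized,positive_underivatized,,Adenine fragment monitored
GSH.pos,GSH,Glutathione reduced,C10H17N3O6S,positive,none,0,308,162,17,none,6.05,pos_underivatized,positive_underivatized,,
GSSG.pos,GSSG,Glutathione oxidized,C20H32N6O12S2,positive,none,0,613,231,34,none,7.45,pos_underivatized,positive_underivatized,,
D.neg,D,Aspartate,C4H7NO4,negative,none,0,131.9,88.1,-20,none,3.26,neg_underivatized,negative_underivatized,,To monitor fate of aspartate into gluconeogenesis
Tre.neg,Tre,Trehalose,C12H22O11,negative,none,0,341.3,179.3,-17,loss:C6H10O5,4.00,neg_underivatized,negative_underivatized,,
G6P.neg,G6P,Glucose 6-phosphate,C6H13O9P,negative,none,0,259,97,-20,product:H3PO4,3.14,neg_underivatized,negative_underivatized,,Sugar-phosphate RTs very close; shallow gradient needed to resolve
G3P.neg,G3P,Glyceraldehyde 3-phosphate,C3H7O6P,negative,none,0,169,97,-20,product:H3PO4,3.17,neg_underivatized,negative_underivatized,,
3PG.neg,3PG,3-Phosphoglycerate,C3H7O7P,negative,none,0,185,97,-20,product:H3PO4,3.02,neg_underivatized,negative_underivatized,,
R5P.neg,R5P,Ribose 5-phosphate,C5H11O8P,negative,none,0,229,97,-20,product:H3PO4,3.20,neg_underivatized,negative_underivatized,,
S7P.neg,S7P,Sedoheptulose 7-phosphate,C7H15O10P,negative,none,0,289,97,-20,product:H3PO4,3.15,neg_underivatized,negative_underivatized,,
Pyr.obha,Pyr,Pyruvate,C3H4O3,positive,OBHA,2,299,181,15,none,9.43,obha_gradient1,obha_gradient1,,Second peak Pyr* of unclear identity observed in standards
Lac.obha,Lac,Lactate,C3H6O3,positive,OBHA,1,196,91.2;124;65.2,25;15;40,product:C7H6;none;none,6.71,obha_gradient1,obha_gradient1,,
MG.obha,MG,Methylglyoxal,C3H4O2,positive,OBHA,2,283,91.2;158.2,25;14,product:C7H6;none,11.30,obha_gradient1,obha_gradient1,,
Cit.obha,Cit,Citrate,C6H8O7,positive,OBHA,3,508,91.2;385,25;7,product:C7H6;loss:C7H9NO,8.70,obha_gradient1,obha_gradient1,,
2-KG.obha,2-KG,2-Ketoglutarate,C5H6O5,positive,OBHA,3,462,91.2;339,25;11,product:C7H6;loss:C7H9NO,9.34,obha_gradient1,obha_gradient1,,
OAA.obha,OAA,Oxaloacetate,C4H4O5,positive,OBHA,3,448,325,10,loss:C7H9NO,9.20,obha_gradient1,obha_gradient1,,
G.obha,G,Glycine,C2H5NO2,positive,OBHA,1,181,166,17,none,8.9,obha_gradient2,obha_gradient2,,
D.obha,D,Aspartate,C4H7NO4,positive,OBHA,2,344,91.2,32,product:C7H6,5.58,obha_gradient2,obha_gradient2,,
E.obha,E,Glutamate,C5H9NO4,positive,OBHA,1,253,91.2,21,product:C7H6,11.9,obha_gradient2,obha_gradient2,,Mono-derivatized despite two carboxyls
Q.obha,Q,Glutamine,C5H10N2O3,positive,OBHA,1,251,91.2,34,product:C7H6,8.04,obha_gradient2,obha_gradient2,printed Q1 251 vs predicted 252; possible in-source ammonia loss or typo,
Suc.obha,Suc,Succinate,C4H6O4,positive,OBHA,2,329,206;91.2,15;34,loss:C7H9NO;product:C7H6,8.60,obha_gradient2,obha_gradient2,,
Fum.obha,Fum,Fumarate,C4H4O4,positive,OBHA,2,327,204;91.2,15;34,loss:C7H9NO;product:C7H6,9.25,obha_gradient2,obha_gradient2,,
Mal.obha,Mal,Malate,C4H6O5,positive,OBHA,2,345,91.2,33,product:C7H6,8.07,obha_gradient2,obha_gradient2,,
Glyox.obha,Glyox,Glyoxalate,C2H2O3,positive,OBHA,2,285,65.1;91.2,51;33,none;product:C7H6,9.37,obha_gradient2,obha_gradient2,,
2-HG.obha,2-HG,2-Hydroxyglutarate,C5H8O5,positive,OBHA,2,359,91.2,35,product:C7H6,7.8,obha_gradient2,obha_gradient2,,
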