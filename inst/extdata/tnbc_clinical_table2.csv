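case,age,tumour_size_cm,histology_grade,nodes_collected,nodes_positive,regional_node_metastasis,t_stage,n_stage,operation
1,67,2 x 1,II,10,9,Yes,T2,N2,Radical mastectomy
2,70,NA,II,12,1,Yes,T2,N1,Radical mastectomy
3,53,1 x 3,III,12,1,Yes,T2,N1,Radical mastectomy
4,42,2.5 x 2.5 x 2,III,2,0,No,T2,N0,Radical mastectomy
5,49,1.3 x 1.7,II,16,0,No,T1,N0,Radical mastectomy
6,65,3.7 x 2.7 x 2.3,II,24,17,Yes,T2,N3,Radical mastectomy
7,46,2 x 1.3,III,15,0,No,T2,N0,Radical mastectomy
8,37,4.8 x 2.1,III,17,0,No,T2,N0,Radical mastectomy
9,36,3.6 x 1.3 x 1.5,III,37,14,Yes,T2,N3,Radical mastectomy
10,40,2.9 x 1.5 x 1.8,III,15,0,No,T2,N0,Radical mastectomy
11,66,3.1 x 1.2,II,16,1,Yes,T2,N1,Radical mastectomy
12,64,3 x 2.5 x 1.5,III,28,0,No,T2,N0,Radical mastectomy
13,46,2.5 x 1.8 x 2,III,24,0,No,T2,N0,Radical mastectomy
14,60,2.8 x 1.9,III,10,3,Yes,T2,N1,Radical mastectomy
15,59,2 x 1.9,III,11,0,No,T1,N0,Radical mastectomy
16,37,2.2 x 1.8,III,9,2,Yes,T2,N1,Radical mastectomy
17,47,2.0,III,27,0,No,T1,N0,Radical mastectomy
18,49,2.6 x 2.4,III,13,4,Yes,T2,N2,Radical mastectomy
19,57,1.7 x 1.2,II,24,8,Yes,T1,N2,Radical mastectomy
20,42,2.3 x 1.7,III,15,1,Yes,T2,N1,Radical mastectomy
21,40,1.7 x 1 x 1,II,24,0,No,T1,N0,Radical mastectomy
22,40,1.9 x 1.1,III,15,0,No,T1,N0,Radical mastectomy
23,37,5.5 x 5 x 1.2,II,20,17,Yes,T3,N3,Radical mastectomy
24,56,8 x 6 x 2,II,31,10,Yes,T3,N3,Radical mastectomy
25,43,2.5 x 2.5 x 2,III,4,0,No,T2,N0,Radical mastectomy
26,30,1.5,II,21,0,No,T1,N0,Radical mastectomy
27,66,2 x 2,II,9,1,Yes,T2,N1,Radical mastectomy
28,52,2.0,II,0,0,No,T2,N0,Breast-conserving tumour resection
29,72,7.5 x 2 x 2,III,4,0,No,T3,N0,Radical mastectomy
30,57,0.7 x 0.9,II,21,9,Yes,T1,N2,Radical mastectomy
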