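"subject","sex","consistency","grade","type","type_name","location"
1,"male","firm","I",1,"fibroblastic","convexity"
2,"female","firm","I",1,"fibroblastic","convexity"
3,"male","firm","I",1,"fibroblastic","convexity"
4,"female","firm","I",1,"fibroblastic","convexity"
5,"male","firm","I",1,"fibroblastic","convexity"
6,"female","firm","I",1,"fibroblastic","convexity"
7,"male","firm","II",1,"fibroblastic","convexity"
8,"female","variable","II",1,"fibroblastic","convexity"
9,"male","variable","I",2,"meningothelial","convexity"
10,"female","variable","II",2,"meningothelial","convexity"
11,"male","variable","II",2,"meningothelial","parasagittal"
12,"female","variable","I",3,"transitional","parasagittal"
13,"male","soft","I",3,"transitional","parasagittal"
14,"female","soft","I",3,"transitional","falx"
15,"male","soft","I",3,"transitional","falx"
16,"female","soft","I",3,"transitional","falx"
17,"male","unknown","I",3,"transitional","falx"
18,"female","unknown","I",3,"transitional","falx"
19,"male","unknown","I",3,"transitional","sphenoid_wing"
20,"female","unknown","II",3,"transitional","sphenoid_wing"
21,"male","unknown","II",4,"clear_cell","sphenoid_wing"
22,"female","unknown","II",4,"clear_cell","sphenoid_wing"
23,"male","unknown","I",5,"microcystic_angiomatous","sphenoid_wing"
24,"female","unknown","I",5,"microcystic_angiomatous","suprasellar"
25,"male","unknown","II",6,"chordoid","tentorial"
26,"female","unknown","I",7,"psammomatous","olfactory_groove_planum"
27,"female","unknown","I",7,"psammomatous","olfactory_groove_planum"
28,"female","unknown","I",7,"psammomatous","clinoid_petroclival"
29,"female","unknown","I",7,"psammomatous","cerebellar"
30,"female","unknown","I",7,"psammomatous","cerebellar"
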