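resource,n_uris,n_triples,special,nonres_n,nonres_d,nonres_aff_n,nonres_aff_d,undef_n,undef_d,undef_aff_n,undef_aff_d,misused_n,misused_d,misused_aff_n,misused_aff_d
rare-disease biobanks and registries,1068,2085,FALSE,5,1068,1039,2085,0,1068,0,2085,0,0,0,2085
Head and neck tumor registry Austria,54,47,FALSE,6,54,10,47,0,54,0,47,0,0,0,47
A biobank of patients with Primary Immune Deficiencies,46,38,FALSE,5,46,9,38,0,46,0,38,0,0,0,38
NeXtProt schema,895,3291,FALSE,0,895,0,3291,1,895,1,3291,0,0,0,3291
Orphanet catalog schema,46,39,FALSE,4,46,13,39,0,46,0,39,0,0,0,39
hPSCreg vocabulary,943,1000,FALSE,95,943,105,1000,1,943,1,1000,0,0,0,1000
Resource Metadata Ontology,257,1627,FALSE,26,257,71,1627,2,257,4,1627,0,0,0,1627
The WikiPathways Ontology,124,149,FALSE,17,124,87,149,1,19,1,149,1,19,2,149
NeXtProt vocabulary,269987,1188696,FALSE,0,269987,0,1188696,0,269987,0,1188696,0,0,0,1188696
The UniProt ontology,396,391,FALSE,0,396,0,391,2,396,2,391,0,0,0,391
ORDO,15070,1142401,FALSE,53,15070,162684,1142401,0,15070,0,1142401,0,0,0,1142401
ATC,6712,66682,FALSE,6,6712,14446,66682,0,6712,0,66682,0,0,0,66682
HPO,39161,1084804,FALSE,300,39161,17870,1084804,60,39161,1855,1084804,1,88,2,1084804
GO,722,4883,FALSE,7,722,23,4883,2,722,7,4883,0,0,0,4883
SNOMED CT,356548,6541868,TRUE,356523,356548,6541865,6541868,0,356548,0,6541868,0,0,0,6541868
NCIT,174590,8775164,FALSE,0,174590,0,8775164,0,174590,0,8775164,0,0,0,8775164
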