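chr1	1	cg00001
chr1	51	cg00002
chr1	101	cg00003
chr1	151	cg00004
chr1	201	cg00005
chr1	251	cg00006
chr1	301	cg00007
chr1	351	cg00008
chr1	401	cg00009
chr1	451	cg00010
chr1	501	cg00011
chr1	551	cg00012
chr1	601	cg00013
chr1	651	cg00014
chr1	701	cg00015
chr1	10701	cg00016
chr1	10751	cg00017
chr1	10801	cg00018
chr1	10851	cg00019
chr1	10901	cg00020
chr1	10951	cg00021
chr1	11001	cg00022
chr1	11051	cg00023
chr1	11101	cg00024
chr1	11151	cg00025
chr1	11201	cg00026
chr1	11251	cg00027
chr1	11301	cg00028
chr1	11351	cg00029
chr1	11401	cg00030
chr1	21401	cg00031
chr1	21451	cg00032
chr1	21501	cg00033
chr1	21551	cg00034
chr1	21601	cg00035
chr1	21651	cg00036
chr1	21701	cg00037
chr1	21751	cg00038
chr1	21801	cg00039
chr1	21851	cg00040
chr1	21901	cg00041
chr1	21951	cg00042
chr1	22001	cg00043
chr1	22051	cg00044
chr1	22101	cg00045
chr1	32101	cg00046
chr1	32151	cg00047
chr1	32201	cg00048
chr1	32251	cg00049
chr1	32301	cg00050
chr1	32351	cg00051
chr1	32401	cg00052
chr1	32451	cg00053
chr1	32501	cg00054
chr1	32551	cg00055
chr1	32601	cg00056
chr1	32651	cg00057
chr1	32701	cg00058
chr1	32751	cg00059
chr1	32801	cg00060
chr1	42801	cg00061
chr1	42851	cg00062
chr1	42901	cg00063
chr1	42951	cg00064
chr1	43001	cg00065
chr1	43051	cg00066
chr1	43101	cg00067
chr1	43151	cg00068
chr1	43201	cg00069
chr1	43251	cg00070
chr1	43301	cg00071
chr1	43351	cg00072
chr1	43401	cg00073
chr1	53401	cg00074
chr1	53451	cg00075
chr1	53501	cg00076
chr1	53551	cg00077
chr1	53601	cg00078
chr1	53651	cg00079
chr1	53701	cg00080
chr1	53751	cg00081
chr1	53801	cg00082
chr1	53851	cg00083
chr1	53901	cg00084
chr1	53951	cg00085
chr1	54001	cg00086
chr1	54051	cg00087
chr1	64051	cg00088
chr1	64101	cg00089
chr1	64151	cg00090
chr1	64201	cg00091
chr1	64251	cg00092
chr1	64301	cg00093
chr1	64351	cg00094
chr1	64401	cg00095
chr1	64451	cg00096
chr1	64501	cg00097
chr1	74501	cg00098
chr1	74551	cg00099
chr1	74601	cg00100
chr1	74651	cg00101
chr1	74701	cg00102
chr1	74751	cg00103
chr1	74801	cg00104
chr1	74851	cg00105
chr1	74901	cg00106
chr1	74951	cg00107
chr1	75001	cg00108
chr1	75051	cg00109
chr1	75101	cg00110
chr1	75151	cg00111
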