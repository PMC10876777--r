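# corpus_total=2345269
word	count
a	50000
an	50000
and	50000
angler	403
are	50000
automobile	403
ball	403
basket	403
beach	403
behind	50000
beside	50000
bird	403
blanket	403
boat	403
book	403
boy	403
by	50000
cap	403
car	403
cloud	403
cottage	403
cup	403
dad	403
daughter	403
dock	403
dog	403
father	403
fisherman	403
fishing	403
flag	403
girl	403
grass	403
hamper	403
hat	403
he	50000
house	403
in	50000
is	50000
it	50000
kite	403
lake	403
lawn	403
man	403
mom	403
mother	403
mug	403
near	50000
on	50000
over	50000
picnic	403
pier	403
plate	403
pole	403
pond	403
puppy	403
radio	403
rod	403
sailboat	403
sand	403
sandwich	403
she	50000
shoe	403
shore	403
shoreline	403
sneaker	403
son	403
the	50000
there	50000
they	50000
tree	403
under	50000
w0001	7
w0002	8
w0003	9
w0004	9
w0005	10
w0006	11
w0007	12
w0008	13
w0009	14
w0010	15
w0011	16
w0012	17
w0013	18
w0014	20
w0015	21
w0016	23
w0017	25
w0018	27
w0019	29
w0020	31
w0021	34
w0022	36
w0023	39
w0024	42
w0025	45
w0026	49
w0027	53
w0028	57
w0029	61
w0030	66
w0031	71
w0032	77
w0033	83
w0034	90
w0035	97
w0036	104
w0037	112
w0038	121
w0039	131
w0040	141
w0041	152
w0042	164
w0043	177
w0044	191
w0045	206
w0046	222
w0047	240
w0048	258
w0049	279
w0050	301
w0051	324
w0052	350
w0053	377
w0054	407
w0055	439
w0056	473
w0057	510
w0058	551
w0059	594
w0060	640
w0061	691
w0062	745
w0063	804
w0064	867
w0065	935
w0066	1008
w0067	1087
w0068	1173
w0069	1265
w0070	1364
w0071	1472
w0072	1587
w0073	1712
w0074	1846
w0075	1991
w0076	2148
w0077	2317
w0078	2499
w0079	2695
w0080	2907
w0081	3135
w0082	3381
w0083	3647
w0084	3934
w0085	4243
w0086	4576
w0087	4935
w0088	5323
w0089	5741
w0090	6192
w0091	6679
w0092	7204
w0093	7770
w0094	8380
w0095	9038
w0096	9749
w0097	10514
w0098	11340
w0099	12231
w0100	13192
w0101	14229
w0102	15347
w0103	16552
w0104	17853
w0105	19255
w0106	20768
w0107	22400
w0108	24160
w0109	26058
w0110	28105
w0111	30313
w0112	32694
w0113	35263
w0114	38033
w0115	41021
w0116	44244
w0117	47720
w0118	51469
w0119	55513
w0120	59874
water	403
woman	403
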