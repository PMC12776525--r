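barcode,sample_id,subset
bc0000016,cardiotox_s1,CD8 PRF1+
bc0000180,no_irae_s1,CD8 GZMK+
bc0000140,no_irae_s1,CD4 Treg
bc0000151,no_irae_s3,CD8 GZMK+
bc0000043,cardiotox_s2,CD8 GZMK+
bc0000028,cardiotox_s3,CD4 Tcm
bc0000038,cardiotox_s3,CD8 GZMK+
bc0000039,cardiotox_s2,CD4 Treg
bc0000098,no_irae_s1,CD4 Tcm
bc0000172,no_irae_s2,CD8 PRF1+
bc0000173,no_irae_s3,CD8 PRF1+
bc0000174,no_irae_s2,CD4 Tcm
bc0000175,no_irae_s1,CD8 PRF1+
bc0000030,cardiotox_s2,CD4 Tcm
bc0000031,cardiotox_s1,CD4 Tcm
bc0000032,cardiotox_s2,CD4 Tcm
bc0000064,cardiotox_s3,CD4 Tcm
bc0000033,cardiotox_s2,CD4 Treg
bc0000034,cardiotox_s2,CD4 Treg
bc0000035,cardiotox_s1,CD4 Treg
bc0000152,no_irae_s2,CD8 GZMK+
bc0000153,no_irae_s3,CD8 GZMK+
bc0000078,cardiotox_s1,CD8 PRF1+
bc0000079,cardiotox_s2,CD8 PRF1+
bc0000001,cardiotox_s2,CD8 GZMK+
bc0000003,cardiotox_s1,CD8 PRF1+
bc0000004,cardiotox_s2,CD8 PRF1+
bc0000005,cardiotox_s2,CD8 PRF1+
bc0000169,no_irae_s3,CD8 GZMK+
bc0000170,no_irae_s3,CD8 GZMK+
bc0000155,no_irae_s1,CD8 PRF1+
bc0000159,no_irae_s1,CD8 PRF1+
bc0000131,no_irae_s1,CD8 GZMK+
bc0000132,no_irae_s1,CD8 GZMK+
bc0000133,no_irae_s1,CD8 GZMK+
bc0000120,no_irae_s3,CD8 PRF1+
bc0000121,no_irae_s3,CD8 PRF1+
bc0000122,no_irae_s1,CD4 Treg
bc0000123,no_irae_s3,CD8 PRF1+
bc0000125,no_irae_s3,CD8 PRF1+
bc0000126,no_irae_s3,CD8 PRF1+
bc0000127,no_irae_s2,CD8 PRF1+
bc0000128,no_irae_s3,CD8 PRF1+
bc0000129,no_irae_s3,CD8 GZMK+
bc0000130,no_irae_s1,CD8 PRF1+
bc0000156,no_irae_s3,CD8 PRF1+
bc0000157,no_irae_s3,CD8 PRF1+
bc0000158,no_irae_s3,CD8 PRF1+
bc0000160,no_irae_s3,CD8 PRF1+
bc0000162,no_irae_s2,CD8 PRF1+
bc0000080,cardiotox_s1,CD4 Treg
bc0000081,cardiotox_s2,CD8 GZMK+
bc0000082,cardiotox_s3,CD4 Treg
bc0000083,cardiotox_s1,CD8 GZMK+
bc0000068,cardiotox_s1,CD4 Treg
bc0000077,cardiotox_s1,CD8 GZMK+
bc0000165,no_irae_s1,CD8 GZMK+
bc0000167,no_irae_s1,CD4 Tcm
bc0000177,no_irae_s2,CD8 GZMK+
bc0000179,no_irae_s3,CD8 GZMK+
bc0000145,no_irae_s1,CD8 GZMK+
bc0000146,no_irae_s1,CD8 GZMK+
bc0000094,no_irae_s1,CD4 Tcm
bc0000096,no_irae_s3,CD8 PRF1+
bc0000176,no_irae_s1,CD8 GZMK+
bc0000178,no_irae_s2,CD8 GZMK+
bc0000069,cardiotox_s2,CD8 GZMK+
bc0000070,cardiotox_s2,CD8 GZMK+
bc0000154,no_irae_s2,CD4 Treg
bc0000051,cardiotox_s3,CD8 GZMK+
bc0000052,cardiotox_s3,CD4 Tcm
bc0000053,cardiotox_s2,CD8 GZMK+
bc0000044,cardiotox_s3,CD4 Treg
bc0000045,cardiotox_s3,CD4 Treg
bc0000046,cardiotox_s1,CD4 Treg
bc0000047,cardiotox_s1,CD4 Treg
bc0000048,cardiotox_s3,CD4 Treg
bc0000049,cardiotox_s1,CD4 Treg
bc0000084,cardiotox_s3,CD4 Tcm
bc0000085,cardiotox_s1,CD4 Tcm
bc0000086,cardiotox_s2,CD8 GZMK+
bc0000087,cardiotox_s3,CD4 Tcm
bc0000088,cardiotox_s3,CD4 Tcm
bc0000089,cardiotox_s1,CD4 Tcm
bc0000090,cardiotox_s3,CD4 Tcm
bc0000059,cardiotox_s2,CD8 PRF1+
bc0000147,no_irae_s1,CD8 GZMK+
bc0000148,no_irae_s3,CD8 GZMK+
bc0000149,no_irae_s2,CD8 GZMK+
bc0000163,no_irae_s2,CD8 GZMK+
bc0000164,no_irae_s1,CD4 Treg
bc0000166,no_irae_s3,CD8 GZMK+
bc0000168,no_irae_s1,CD8 GZMK+
bc0000042,cardiotox_s3,CD8 PRF1+
bc0000103,no_irae_s2,CD8 GZMK+
bc0000104,no_irae_s3,CD8 GZMK+
bc0000091,no_irae_s3,CD8 PRF1+
bc0000092,no_irae_s2,CD8 GZMK+
bc0000093,no_irae_s3,CD8 GZMK+
bc0000060,cardiotox_s2,CD8 GZMK+
bc0000061,cardiotox_s2,CD8 GZMK+
bc0000063,cardiotox_s3,CD8 GZMK+
bc0000109,no_irae_s3,CD8 GZMK+
bc0000110,no_irae_s2,CD8 GZMK+
bc0000111,no_irae_s1,CD8 GZMK+
bc0000113,no_irae_s1,CD8 GZMK+
bc0000114,no_irae_s3,CD8 GZMK+
bc0000116,no_irae_s1,CD8 GZMK+
bc0000138,no_irae_s3,CD8 PRF1+
bc0000134,no_irae_s2,CD4 Tcm
bc0000136,no_irae_s1,CD4 Tcm
bc0000097,no_irae_s1,CD4 Tcm
bc0000099,no_irae_s1,CD8 PRF1+
bc0000037,cardiotox_s3,CD4 Tcm
bc0000055,cardiotox_s3,CD4 Treg
bc0000056,cardiotox_s2,CD4 Treg
bc0000057,cardiotox_s3,CD4 Treg
bc0000118,no_irae_s2,CD8 PRF1+
bc0000112,no_irae_s3,CD8 GZMK+
bc0000139,no_irae_s3,CD4 Treg
bc0000024,cardiotox_s3,CD4 Tcm
bc0000025,cardiotox_s1,CD8 GZMK+
bc0000026,cardiotox_s3,CD8 GZMK+
bc0000027,cardiotox_s3,CD8 PRF1+
bc0000050,cardiotox_s2,CD8 GZMK+
bc0000101,no_irae_s1,CD8 PRF1+
bc0000100,no_irae_s2,CD8 GZMK+
bc0000143,no_irae_s1,CD4 Tcm
bc0000144,no_irae_s1,CD4 Tcm
bc0000017,cardiotox_s3,CD8 GZMK+
bc0000007,cardiotox_s3,CD8 GZMK+
bc0000008,cardiotox_s1,CD8 GZMK+
bc0000009,cardiotox_s1,CD8 GZMK+
bc0000010,cardiotox_s1,CD8 GZMK+
bc0000011,cardiotox_s2,CD8 GZMK+
bc0000012,cardiotox_s2,CD8 GZMK+
bc0000013,cardiotox_s3,CD8 GZMK+
bc0000014,cardiotox_s3,CD8 GZMK+
bc0000015,cardiotox_s1,CD8 GZMK+
bc0000040,cardiotox_s3,CD4 Treg
bc0000041,cardiotox_s1,CD4 Treg
bc0000072,cardiotox_s1,CD8 PRF1+
bc0000073,cardiotox_s1,CD8 PRF1+
bc0000074,cardiotox_s3,CD8 PRF1+
bc0000075,cardiotox_s1,CD8 PRF1+
bc0000076,cardiotox_s2,CD8 PRF1+
bc0000065,cardiotox_s1,CD8 GZMK+
bc0000066,cardiotox_s2,CD8 PRF1+
bc0000067,cardiotox_s3,CD8 PRF1+
bc0000105,no_irae_s2,CD8 PRF1+
bc0000106,no_irae_s2,CD8 PRF1+
bc0000107,no_irae_s3,CD8 PRF1+
bc0000108,no_irae_s1,CD8 PRF1+
bc0000018,cardiotox_s2,CD4 Treg
bc0000020,cardiotox_s3,CD4 Treg
bc0000021,cardiotox_s3,CD4 Treg
bc0000022,cardiotox_s3,CD4 Treg
bc0000023,cardiotox_s3,CD4 Treg
bc0000150,no_irae_s3,CD8 PRF1+
bc0000029,cardiotox_s2,CD4 Tcm
bc0000054,cardiotox_s1,CD8 GZMK+
bc0000058,cardiotox_s3,CD4 Treg
bc0000141,no_irae_s1,CD4 Treg
bc0000036,cardiotox_s1,CD4 Treg
bc0000115,no_irae_s3,CD8 GZMK+
bc0000102,no_irae_s3,CD8 PRF1+
bc0000161,no_irae_s1,CD8 PRF1+
bc0000095,no_irae_s1,CD4 Tcm
bc0000171,no_irae_s1,CD8 GZMK+
bc0000124,no_irae_s1,CD8 PRF1+
bc0000135,no_irae_s1,CD4 Tcm
bc0000137,no_irae_s3,CD4 Tcm
bc0000142,no_irae_s3,CD4 Treg
bc0000062,cardiotox_s2,CD8 GZMK+
bc0000117,no_irae_s1,CD8 GZMK+
bc0000119,no_irae_s1,CD8 GZMK+
bc0000002,cardiotox_s3,CD8 PRF1+
bc0000006,cardiotox_s2,CD4 Treg
bc0000019,cardiotox_s1,CD4 Treg
bc0000071,cardiotox_s1,CD8 PRF1+
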