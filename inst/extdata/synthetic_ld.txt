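rs1001 rs1002 rs1003 rs1004 rs1005 rs1006 rs1007 rs1008 rs2001 rs2002 rs2003 rs2004 rs2005 rs2006
1.0000000 0.6000000 0.3600000 0.2160000 0.1296000 0.0777600 0.0466560 0.0279936 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.6000000 1.0000000 0.6000000 0.3600000 0.2160000 0.1296000 0.0777600 0.0466560 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.3600000 0.6000000 1.0000000 0.6000000 0.3600000 0.2160000 0.1296000 0.0777600 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.2160000 0.3600000 0.6000000 1.0000000 0.6000000 0.3600000 0.2160000 0.1296000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.1296000 0.2160000 0.3600000 0.6000000 1.0000000 0.6000000 0.3600000 0.2160000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.0777600 0.1296000 0.2160000 0.3600000 0.6000000 1.0000000 0.6000000 0.3600000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.0466560 0.0777600 0.1296000 0.2160000 0.3600000 0.6000000 1.0000000 0.6000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.0279936 0.0466560 0.0777600 0.1296000 0.2160000 0.3600000 0.6000000 1.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 1.0000000 0.3000000 0.3000000 0.3000000 0.3000000 0.3000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.3000000 1.0000000 0.3000000 0.3000000 0.3000000 0.3000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.3000000 0.3000000 1.0000000 0.3000000 0.3000000 0.3000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.3000000 0.3000000 0.3000000 1.0000000 0.3000000 0.3000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.3000000 0.3000000 0.3000000 0.3000000 1.0000000 0.3000000
0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.0000000 0.3000000 0.3000000 0.3000000 0.3000000 0.3000000 1.0000000
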