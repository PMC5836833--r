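AC  M00001
ID  M00001
BF  TFG001
P0       A       C       G       T
01      94       2       4       0  A
02       0     100       0       0  C
03       0       1      99       0  G
04       0       0      98       2  G
05      98       0       1       1  A
06       0      91       8       1  C
07       0       0     100       0  G
08      99       0       1       0  A
//
AC  M00002
ID  M00002
BF  TFG002
P0       A       C       G       T
01      98       0       1       1  A
02      74       8      14       4  A
03       2       0       0      98  T
04      93       0       0       7  A
05      90       1       9       0  A
06       5      89       1       5  C
07       0       0     100       0  G
08      90       1       3       6  A
//
AC  M00003
ID  M00003
BF  TFG003
P0       A       C       G       T
01      88       4       0       8  A
02       0       0     100       0  G
03       0       2       0      98  T
04      91       3       6       0  A
05       1       5      94       0  G
06       3       0       1      96  T
07     100       0       0       0  A
08      81      17       0       2  A
09       1       0       3      96  T
10       0       0     100       0  G
11      97       0       3       0  A
12       0       3       0      97  T
//
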