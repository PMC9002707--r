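# id type filters size stride sources split declared_in declared_out
input 320 320 1
0 conv 27 3 2 - - 320x320x1 160x160x27
1 conv 49 3 2 - - 160x160x27 80x80x49
2 conv 45 3 1 - - 80x80x49 80x80x45
3 route - - - 2 yes - -
4 conv 31 3 1 - - 80x80x22 80x80x31
5 conv 28 3 1 - - 80x80x31 80x80x28
6 route - - - 4,5 - - -
7 conv 64 1 1 - - 80x80x59 80x80x64
8 route - - - 2,7 - - -
9 maxpool - 2 2 - - 80x80x109 40x40x109
10 conv 86 3 1 - - 40x40x109 40x40x86
11 route - - - 10 yes - -
12 conv 56 3 1 - - 40x40x43 40x40x56
13 conv 47 3 1 - - 40x40x56 40x40x47
14 route - - - 12,13 - - -
15 conv 128 1 1 - - 40x40x128 40x40x128
16 route - - - 10,15 - - -
17 maxpool - 2 2 - - 40x40x214 20x20x214
18 conv 164 3 1 - - 20x20x214 20x20x164
19 route - - - 18 yes - -
20 conv 83 3 1 - - 20x20x82 20x20x83
21 conv 83 3 1 - - 20x20x83 20x20x83
22 route - - - 20,21 - - -
23 conv 256 1 1 - - 20x20x166 20x20x256
24 route - - - 18,23 - - -
25 maxpool - 2 2 - - 20x20x420 10x10x420
26 conv 189 3 1 - - 10x10x420 10x10x189
27 conv 256 1 1 - - 10x10x189 10x10x256
28 conv 174 3 1 - - 10x10x256 10x10x174
29 conv 18 1 1 - - 10x10x174 10x10x18
30 yolo - - - - - - -
31 route - - - 27 - - -
32 conv 128 1 1 - - 10x10x256 10x10x128
33 upsample - - 2 - - 10x10x128 20x20x128
34 route - - - 23,33 - - -
35 conv 120 3 1 - - 20x20x384 20x20x120
36 conv 18 1 1 - - 20x20x256 20x20x18
37 yolo - - - - - - -
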