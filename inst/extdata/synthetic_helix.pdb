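HEADER    SYNTHETIC TEST STRUCTURE                01JAN26   XXXX
TITLE     SYNTHETIC SINGLE-CHAIN ALPHA-HELIX FIXTURE (NOT A REAL STRUCTURE)
HELIX    1   1 ALA A    3  ALA A   14  1                                  12
ATOM      1  CA  SER A   1       2.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ILE A   2      -0.399   2.265   1.500  1.00  0.00           C
ATOM      3  CA  ALA A   3      -2.161  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  GLU A   4       1.150  -1.992   4.500  1.00  0.00           C
ATOM      5  CA  LEU A   5       1.762   1.478   6.000  1.00  0.00           C
ATOM      6  CA  LYS A   6      -1.762   1.478   7.500  1.00  0.00           C
ATOM      7  CA  ALA A   7      -1.150  -1.992   9.000  1.00  0.00           C
ATOM      8  CA  ARG A   8       2.161  -0.787  10.500  1.00  0.00           C
ATOM      9  CA  ILE A   9       0.399   2.265  12.000  1.00  0.00           C
ATOM     10  CA  LYS A  10      -2.300   0.000  13.500  1.00  0.00           C
ATOM     11  CA  GLU A  11       0.399  -2.265  15.000  1.00  0.00           C
ATOM     12  CA  LEU A  12       2.161   0.787  16.500  1.00  0.00           C
ATOM     13  CA  GLU A  13      -1.150   1.992  18.000  1.00  0.00           C
ATOM     14  CA  ALA A  14      -1.762  -1.478  19.500  1.00  0.00           C
ATOM     15  CA  ARG A  15       1.762  -1.478  21.000  1.00  0.00           C
ATOM     16  CA  MET A  16       1.150   1.992  22.500  1.00  0.00           C
TER      17      MET A  16
END
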