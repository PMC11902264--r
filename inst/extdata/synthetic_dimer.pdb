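HEADER    SYNTHETIC TEST STRUCTURE                01JAN26   XXXX
TITLE     SYNTHETIC TWO-CHAIN POLYPEPTIDE FIXTURE (NOT A REAL STRUCTURE)
HELIX    1   1 ALA A    3  GLY A   10  1                                   8
SHEET    1   A 1 VAL B   2  TYR B   6  0
ATOM      1  CA  MET A   1       0.000   0.000   2.000  1.00  0.00           C
ATOM      2  CA  LYS A   2       1.500   1.683   1.081  1.00  0.00           C
ATOM      3  CA  ALA A   3       3.000   1.819  -0.832  1.00  0.00           C
ATOM      4  CA  ALA A   4       4.500   0.282  -1.980  1.00  0.00           C
ATOM      5  CA  LEU A   5       6.000  -1.514  -1.307  1.00  0.00           C
ATOM      6  CA  GLU A   6       7.500  -1.918   0.567  1.00  0.00           C
ATOM      7  CA  LYS A   7       9.000  -0.559   1.920  1.00  0.00           C
ATOM      8  CA  LEU A   8      10.500   1.314   1.508  1.00  0.00           C
ATOM      9  CA  ILE A   9      12.000   1.979  -0.291  1.00  0.00           C
ATOM     10  CA  GLY A  10      13.500   0.824  -1.822  1.00  0.00           C
ATOM     11  CA  SER A  11      15.000  -1.088  -1.678  1.00  0.00           C
ATOM     12  CA  ASP A  12      16.500  -2.000   0.009  1.00  0.00           C
TER      13      ASP A  12
ATOM     14  CA  GLY B   1       0.000   0.000  22.000  1.00  0.00           C
ATOM     15  CA  VAL B   2       1.500   1.683  21.081  1.00  0.00           C
ATOM     16  CA  ILE B   3       3.000   1.819  19.168  1.00  0.00           C
ATOM     17  CA  PHE B   4       4.500   0.282  18.020  1.00  0.00           C
ATOM     18  CA  VAL B   5       6.000  -1.514  18.693  1.00  0.00           C
ATOM     19  CA  TYR B   6       7.500  -1.918  20.567  1.00  0.00           C
ATOM     20  CA  ALA B   7       9.000  -0.559  21.920  1.00  0.00           C
ATOM     21  CA  ASP B   8      10.500   1.314  21.508  1.00  0.00           C
TER      22      ASP B   8
END
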