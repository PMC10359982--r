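HEADER    PROTEIN                                             SYN1
EXPDTA    X-RAY DIFFRACTION
REMARK   2 RESOLUTION.    1.20 ANGSTROMS.
REMARK 200  TEMPERATURE           (KELVIN) : 100
DBREF  SYN1 A    2     7  UNP    SYNTH001 SYNTH001         2      7
SSBOND   1 CYS A    2    CYS A    3 
ATOM      1  N   CYS A   2      -3.668  -0.590  -1.216  1.00 10.00           N
ATOM      2  CA  CYS A   2      -2.436  -1.206  -0.702  1.00 10.00           C
ATOM      3  C   CYS A   2      -2.894  -2.581  -0.244  1.00 10.00           C
ATOM      4  O   CYS A   2      -2.894  -3.686   0.296  1.00 10.00           O
ATOM      5  CB  CYS A   2      -1.810   0.000   0.000  1.00 10.00           C
ATOM      6  SG  CYS A   2       0.000   0.000   0.000  1.00 10.00           S
ATOM      7  N   CYS A   3       2.317  -3.220   2.616  1.00 10.00           N
ATOM      8  CA  CYS A   3       0.909  -3.642   2.616  1.00 10.00           C
ATOM      9  C   CYS A   3       0.148  -4.859   3.118  1.00 10.00           C
ATOM     10  O   CYS A   3      -0.834  -5.350   3.670  1.00 10.00           O
ATOM     11  CB  CYS A   3       0.602  -2.414   1.756  1.00 10.00           C
ATOM     12  SG  CYS A   3       0.496  -1.989   0.000  1.00 10.00           S
ATOM     13  N   GLY A   5       6.781   1.441   0.533  1.00 10.00           N
ATOM     14  CA  GLY A   5       5.404   1.149   0.956  1.00 10.00           C
ATOM     15  C   GLY A   5       4.235   0.900   0.000  1.00 10.00           C
ATOM     16  O   GLY A   5       3.032   0.645   0.000  1.00 10.00           O
ATOM     17  N   GLY A   7      -2.894  -6.381   1.614  1.00 10.00           N
ATOM     18  CA  GLY A   7      -4.082  -7.124   2.059  1.00 10.00           C
ATOM     19  C   GLY A   7      -3.612  -8.535   2.373  1.00 10.00           C
ATOM     20  O   GLY A   7      -2.499  -8.906   2.002  1.00 10.00           O
TER
END
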