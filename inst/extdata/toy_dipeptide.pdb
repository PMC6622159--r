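REMARK synthetic two-residue fixture (GLY-ALA), hand-built coordinates
ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      6  CA  ALA A   2       3.988   2.839   0.000  1.00  0.00           C
ATOM      7  C   ALA A   2       5.504   2.693   0.000  1.00  0.00           C
ATOM      8  O   ALA A   2       6.030   1.581   0.000  1.00  0.00           O
ATOM      9  CB  ALA A   2       3.542   3.659   1.211  1.00  0.00           C
TER      10      ALA A   2
END
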