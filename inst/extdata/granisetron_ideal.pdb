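HETATM    1  O1  GRN L 401       0.844  -1.842  -1.170  1.00  0.00           O
HETATM    2  C1  GRN L 401       1.312  -1.019  -0.386  1.00  0.00           C
HETATM    3  N1  GRN L 401       0.501  -0.055   0.214  1.00  0.00           N
HETATM    4  C2  GRN L 401      -0.944  -0.128   0.053  1.00  0.00           C
HETATM    5  C3  GRN L 401      -1.652   0.768   1.076  1.00  0.00           C
HETATM    6  C4  GRN L 401      -3.176   0.795   0.876  1.00  0.00           C
HETATM    7  C5  GRN L 401      -3.831  -0.567   1.141  1.00  0.00           C
HETATM    8  C6  GRN L 401      -4.285  -1.362  -0.079  1.00  0.00           C
HETATM    9  C7  GRN L 401      -3.530  -1.098  -1.379  1.00  0.00           C
HETATM   10  C8  GRN L 401      -2.895   0.289  -1.540  1.00  0.00           C
HETATM   11  C9  GRN L 401      -1.370   0.264  -1.372  1.00  0.00           C
HETATM   12  N2  GRN L 401      -3.442   1.271  -0.531  1.00  0.00           N
HETATM   13  C10 GRN L 401      -4.846   1.745  -0.797  1.00  0.00           C
HETATM   14  C11 GRN L 401       2.719  -0.997   0.040  1.00  0.00           C
HETATM   15  N3  GRN L 401       3.400  -2.143   0.210  1.00  0.00           N
HETATM   16  N4  GRN L 401       4.624  -1.754   0.606  1.00  0.00           N
HETATM   17  C12 GRN L 401       5.639  -2.750   0.860  1.00  0.00           C
HETATM   18  C13 GRN L 401       4.766  -0.396   0.729  1.00  0.00           C
HETATM   19  C14 GRN L 401       5.850   0.403   1.120  1.00  0.00           C
HETATM   20  C15 GRN L 401       5.668   1.788   1.111  1.00  0.00           C
HETATM   21  C16 GRN L 401       4.456   2.351   0.718  1.00  0.00           C
HETATM   22  C17 GRN L 401       3.383   1.539   0.330  1.00  0.00           C
HETATM   23  C18 GRN L 401       3.537   0.136   0.347  1.00  0.00           C
CONECT    1    2
CONECT    2    3
CONECT    3    4
CONECT    4    5
CONECT    5    6
CONECT    6    7
CONECT    7    8
CONECT    8    9
CONECT    9   10
CONECT   10   11
CONECT   10   12
CONECT   12   13
CONECT    2   14
CONECT   14   15
CONECT   15   16
CONECT   16   17
CONECT   16   18
CONECT   18   19
CONECT   19   20
CONECT   20   21
CONECT   21   22
CONECT   22   23
CONECT   11    4
CONECT   23   14
CONECT   12    6
CONECT   23   18
END
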