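ATOM      1  CA  SCF A   1     -13.300 -13.300  -4.000
ATOM      2  CA  SCF A   2      -9.500 -13.300  -4.000
ATOM      3  CA  SCF A   3      -5.700 -13.300  -4.000
ATOM      4  CA  SCF A   4      -1.900 -13.300  -4.000
ATOM      5  CA  SCF A   5       1.900 -13.300  -4.000
ATOM      6  CA  SCF A   6       5.700 -13.300  -4.000
ATOM      7  CA  SCF A   7       9.500 -13.300  -4.000
ATOM      8  CA  SCF A   8      13.300 -13.300  -4.000
ATOM      9  CA  SCF A   9     -13.300  -9.500  -4.000
ATOM     10  CA  SCF A  10      -9.500  -9.500  -4.000
ATOM     11  CA  SCF A  11      -5.700  -9.500  -4.000
ATOM     12  CA  SCF A  12      -1.900  -9.500  -4.000
ATOM     13  CA  SCF A  13       1.900  -9.500  -4.000
ATOM     14  CA  SCF A  14       5.700  -9.500  -4.000
ATOM     15  CA  SCF A  15       9.500  -9.500  -4.000
ATOM     16  CA  SCF A  16      13.300  -9.500  -4.000
ATOM     17  CA  SCF A  17     -13.300  -5.700  -4.000
ATOM     18  CA  SCF A  18      -9.500  -5.700  -4.000
ATOM     19  CA  SCF A  19      -5.700  -5.700  -4.000
ATOM     20  CA  SCF A  20      -1.900  -5.700  -4.000
ATOM     21  CA  SCF A  21       1.900  -5.700  -4.000
ATOM     22  CA  SCF A  22       5.700  -5.700  -4.000
ATOM     23  CA  SCF A  23       9.500  -5.700  -4.000
ATOM     24  CA  SCF A  24      13.300  -5.700  -4.000
ATOM     25  CA  SCF A  25     -13.300  -1.900  -4.000
ATOM     26  CA  SCF A  26      -9.500  -1.900  -4.000
ATOM     27  CA  SCF A  27      -5.700  -1.900  -4.000
ATOM     28  CA  SCF A  28      -1.900  -1.900  -4.000
ATOM     29  CA  SCF A  29       1.900  -1.900  -4.000
ATOM     30  CA  SCF A  30       5.700  -1.900  -4.000
ATOM     31  CA  SCF A  31       9.500  -1.900  -4.000
ATOM     32  CA  SCF A  32      13.300  -1.900  -4.000
ATOM     33  CA  SCF A  33     -13.300   1.900  -4.000
ATOM     34  CA  SCF A  34      -9.500   1.900  -4.000
ATOM     35  CA  SCF A  35      -5.700   1.900  -4.000
ATOM     36  CA  SCF A  36      -1.900   1.900  -4.000
ATOM     37  CA  SCF A  37       1.900   1.900  -4.000
ATOM     38  CA  SCF A  38       5.700   1.900  -4.000
ATOM     39  CA  SCF A  39       9.500   1.900  -4.000
ATOM     40  CA  SCF A  40      13.300   1.900  -4.000
ATOM     41  CA  SCF A  41     -13.300   5.700  -4.000
ATOM     42  CA  SCF A  42      -9.500   5.700  -4.000
ATOM     43  CA  SCF A  43      -5.700   5.700  -4.000
ATOM     44  CA  SCF A  44      -1.900   5.700  -4.000
ATOM     45  CA  SCF A  45       1.900   5.700  -4.000
ATOM     46  CA  SCF A  46       5.700   5.700  -4.000
ATOM     47  CA  SCF A  47       9.500   5.700  -4.000
ATOM     48  CA  SCF A  48      13.300   5.700  -4.000
ATOM     49  CA  SCF A  49     -13.300   9.500  -4.000
ATOM     50  CA  SCF A  50      -9.500   9.500  -4.000
ATOM     51  CA  SCF A  51      -5.700   9.500  -4.000
ATOM     52  CA  SCF A  52      -1.900   9.500  -4.000
ATOM     53  CA  SCF A  53       1.900   9.500  -4.000
ATOM     54  CA  SCF A  54       5.700   9.500  -4.000
ATOM     55  CA  SCF A  55       9.500   9.500  -4.000
ATOM     56  CA  SCF A  56      13.300   9.500  -4.000
ATOM     57  CA  SCF A  57     -13.300  13.300  -4.000
ATOM     58  CA  SCF A  58      -9.500  13.300  -4.000
ATOM     59  CA  SCF A  59      -5.700  13.300  -4.000
ATOM     60  CA  SCF A  60      -1.900  13.300  -4.000
ATOM     61  CA  SCF A  61       1.900  13.300  -4.000
ATOM     62  CA  SCF A  62       5.700  13.300  -4.000
ATOM     63  CA  SCF A  63       9.500  13.300  -4.000
ATOM     64  CA  SCF A  64      13.300  13.300  -4.000
ATOM     65  CA  Q00 C   1     -15.200   0.000   0.000
ATOM     66  CA  Q00 C   2     -11.400   0.000   0.000
ATOM     67  CA  Q00 C   3      -7.600   0.000   0.000
ATOM     68  CA  Q00 C   4      -3.800   0.000   0.000
ATOM     69  CA  Q00 C   5       0.000   0.000   0.000
ATOM     70  CA  Q00 C   6       3.800   0.000   0.000
ATOM     71  CA  Q00 C   7       7.600   0.000   0.000
ATOM     72  CA  Q00 C   8      11.400   0.000   0.000
ATOM     73  CA  Q00 C   9      15.200   0.000   0.000
END
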