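MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF AP1
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
0.008500  0.010000  0.011500  0.970000
0.009208  0.010833  0.967500  0.012458
0.965000  0.009917  0.011667  0.013417
0.015937  0.510125  0.452375  0.021562
0.011333  0.013333  0.015333  0.960000
0.012042  0.957500  0.014167  0.016292
0.955000  0.012750  0.015000  0.017250

MOTIF IRF
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.970000  0.008500  0.010000  0.011500
0.967500  0.009208  0.010833  0.012458
0.280000  0.260000  0.240000  0.220000
0.010625  0.012500  0.014375  0.962500
0.011333  0.013333  0.960000  0.015333
0.957500  0.012042  0.014167  0.016292
0.955000  0.012750  0.015000  0.017250
0.952500  0.013458  0.015833  0.018208

MOTIF GAS
letter-probability matrix: alength= 4 w= 9 nsites= 20 E= 0
0.008500  0.010000  0.011500  0.970000
0.009208  0.010833  0.012458  0.967500
0.009917  0.965000  0.011667  0.013417
0.280000  0.260000  0.240000  0.220000
0.280000  0.260000  0.240000  0.220000
0.280000  0.260000  0.240000  0.220000
0.012750  0.015000  0.955000  0.017250
0.952500  0.013458  0.015833  0.018208
0.950000  0.014167  0.016667  0.019167

MOTIF CTCF
letter-probability matrix: alength= 4 w= 12 nsites= 20 E= 0
0.008500  0.970000  0.010000  0.011500
0.009208  0.967500  0.010833  0.012458
0.965000  0.009917  0.011667  0.013417
0.015937  0.510125  0.452375  0.021562
0.017000  0.508800  0.023000  0.451200
0.957500  0.012042  0.014167  0.016292
0.012750  0.015000  0.955000  0.017250
0.504825  0.020187  0.447675  0.027312
0.021250  0.028750  0.503500  0.446500
0.014875  0.017500  0.947500  0.020125
0.015583  0.018333  0.945000  0.021083
0.016292  0.942500  0.019167  0.022042

MOTIF ETS
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.008500  0.970000  0.010000  0.011500
0.967500  0.009208  0.010833  0.012458
0.009917  0.011667  0.965000  0.013417
0.010625  0.012500  0.962500  0.014375
0.960000  0.011333  0.013333  0.015333
0.957500  0.012042  0.014167  0.016292
0.012750  0.015000  0.955000  0.017250
0.013458  0.015833  0.018208  0.952500

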