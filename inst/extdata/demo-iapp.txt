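-1.5015763724157871e+00
1.1867263589405166e+00
4.5650413038019426e+00
-3.3346117441634187e+00
-3.3360294876046295e+00
1.4434158786764151e+00
3.1602303014625956e+00
-2.1539923022352792e+00
-5.7173697340455005e+00
1.9099490849345830e+00
-3.9378674642466143e+00
-9.1869446537006283e-01
-3.1759313879456554e+00
-2.0488150374761656e+00
-3.4605190026291242e+00
-7.4944751628917343e+00
-3.1998039670740930e-01
2.2302587505214966e+00
2.2557460070882840e-01
3.2648684530968470e+00
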