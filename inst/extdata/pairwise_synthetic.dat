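0.2302235529 -0.7188621625
0.4869625002 -0.4084121302
0.4942218714 0.05044424943
0.5032642518 0.2224351553
0.2127817437 0.2439850866
0.0160253193 0.4389246839
0.3774388789 -0.2091690758
0.2302235529 -0.7188621625
0.569183544 1.557668656
0.3632636707 -0.08621814492
0.5153027388 -0.739890843
0.1497393994 -0.6148277622
0.2342006489 -1.626513898
0.4090151769 0.0514884923
0.4869625002 -0.4084121302
0.569183544 1.557668656
0.5164238534 -0.4247070688
0.3789693633 -0.6663812541
0.4206912303 -0.2314779274
0.4982076875 -1.19566152
0.5748067343 0.07268876533
0.4942218714 0.05044424943
0.3632636707 -0.08621814492
0.5164238534 -0.4247070688
0.5945843911 0.4685560934
0.3093578888 -0.6216809775
0.4994964361 -0.09919131155
0.6729718048 -0.6829209156
0.5032642518 0.2224351553
0.5153027388 -0.739890843
0.3789693633 -0.6663812541
0.5945843911 0.4685560934
0.4122797504 -0.005179410094
0.5192767486 0.5203917983
0.3172887142 -0.1957597272
0.2127817437 0.2439850866
0.1497393994 -0.6148277622
0.4206912303 -0.2314779274
0.3093578888 -0.6216809775
0.4122797504 -0.005179410094
0.2231618135 0.5010350224
0.3907429016 0.236440695
0.0160253193 0.4389246839
0.2342006489 -1.626513898
0.4982076875 -1.19566152
0.4994964361 -0.09919131155
0.5192767486 0.5203917983
0.2231618135 0.5010350224
0.39005646 0.1627954313
0.3774388789 -0.2091690758
0.4090151769 0.0514884923
0.5748067343 0.07268876533
0.6729718048 -0.6829209156
0.3172887142 -0.1957597272
0.3907429016 0.236440695
0.39005646 0.1627954313
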