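# SWC written by motorunit (soma as single equivalent-area sample)
1 1 0.000000000 0.000000000 0.000000000 24.400000000 -1
2 3 356.512980991 464.998721195 -77.777628783 4.088491546 1
3 3 -164.403889088 372.862801831 -235.870744229 2.220079625 2
4 3 219.672006296 128.536443743 -274.041078121 1.238846533 3
5 3 -368.358137819 -19.816988624 -122.416420145 1.238846533 3
6 3 874.429736487 654.125923198 -106.587039741 2.220079625 2
7 3 1302.931624554 810.601577409 -130.422698384 1.238846533 6
8 3 1065.567334260 245.641613117 -179.206762928 1.238846533 6
9 3 165.466593031 527.467949852 98.162281801 3.585709334 1
10 3 313.691301003 999.972891176 186.095895997 1.974829648 9
11 3 -131.409572447 742.050880688 335.134605904 1.077489180 10
12 3 16.048299766 1423.380121868 48.306023714 1.077489180 10
13 3 102.389188268 40.888936042 -12.408548272 1.974829648 9
14 3 35.219570719 -477.257401582 -130.152776905 1.077489180 13
15 3 -410.177842999 62.113382894 141.460387531 1.077489180 13
16 3 -25.605940514 554.489489889 -120.435636966 4.030203648 1
17 3 350.916196980 179.756105046 -59.624307448 2.199493012 16
18 3 328.496595049 665.246322875 -165.073237845 1.213324402 17
19 3 843.696126005 246.024920329 -49.661739945 1.213324402 17
20 3 -447.542184673 848.106234628 26.707356788 2.199493012 16
21 3 -839.986399518 1121.200083402 163.565513567 1.213324402 20
22 3 -203.003631955 1274.781943337 -47.262927200 1.213324402 20
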