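# SWC export: one point per section distal end; x = path distance (um)
1 1 0 0 0 3.0500 -1
2 1 33.6000 1.0000 0 3.0500 1
3 2 213.6000 2.0000 0 0.5000 2
4 3 46.4000 3.0000 0 0.5000 2
5 3 43.7000 4.0000 0 0.5000 2
6 3 40.9000 5.0000 0 0.5000 2
7 3 77.8000 6.0000 0 1.0000 4
8 3 77.8000 7.0000 0 1.0000 4
9 3 77.8000 8.0000 0 1.0000 4
10 3 77.8000 9.0000 0 1.0000 4
11 3 77.8000 10.0000 0 1.0000 4
12 3 77.8000 11.0000 0 1.0000 4
13 3 77.8000 12.0000 0 1.0000 4
14 3 77.8000 13.0000 0 1.0000 4
15 3 77.8000 14.0000 0 1.0000 4
16 3 77.8000 15.0000 0 1.0000 4
17 3 77.8000 16.0000 0 1.0000 4
18 3 77.8000 17.0000 0 1.0000 4
19 3 77.8000 18.0000 0 1.0000 4
20 3 77.8000 19.0000 0 1.0000 4
21 3 77.8000 20.0000 0 1.0000 4
22 3 77.8000 21.0000 0 1.0000 4
23 3 77.8000 22.0000 0 1.0000 4
24 3 77.8000 23.0000 0 1.0000 4
25 3 77.8000 24.0000 0 1.0000 4
26 3 77.8000 25.0000 0 1.0000 4
27 3 77.8000 26.0000 0 1.0000 4
28 3 77.8000 27.0000 0 1.0000 4
29 3 77.8000 28.0000 0 1.0000 4
30 3 77.8000 29.0000 0 1.0000 4
31 3 77.8000 30.0000 0 1.0000 4
32 3 77.8000 31.0000 0 1.0000 4
33 3 77.8000 32.0000 0 1.0000 4
34 3 77.8000 33.0000 0 1.0000 4
35 3 77.8000 34.0000 0 1.0000 4
36 3 77.8000 35.0000 0 1.0000 4
37 3 77.8000 36.0000 0 1.0000 4
38 3 77.8000 37.0000 0 1.0000 4
39 3 77.8000 38.0000 0 1.0000 4
40 3 77.8000 39.0000 0 1.0000 4
41 3 77.8000 40.0000 0 1.0000 4
42 3 77.8000 41.0000 0 1.0000 4
43 3 77.8000 42.0000 0 1.0000 4
44 3 77.8000 43.0000 0 1.0000 4
45 3 77.8000 44.0000 0 1.0000 4
46 3 77.8000 45.0000 0 1.0000 4
47 3 77.8000 46.0000 0 1.0000 4
48 3 77.8000 47.0000 0 1.0000 4
49 3 77.8000 48.0000 0 1.0000 4
50 3 77.8000 49.0000 0 1.0000 4
51 3 77.8000 50.0000 0 1.0000 4
52 3 77.8000 51.0000 0 1.0000 4
53 3 75.1000 52.0000 0 1.0000 5
54 3 75.1000 53.0000 0 1.0000 5
55 3 75.1000 54.0000 0 1.0000 5
56 3 75.1000 55.0000 0 1.0000 5
57 3 75.1000 56.0000 0 1.0000 5
58 3 75.1000 57.0000 0 1.0000 5
59 3 75.1000 58.0000 0 1.0000 5
60 3 75.1000 59.0000 0 1.0000 5
61 3 75.1000 60.0000 0 1.0000 5
62 3 75.1000 61.0000 0 1.0000 5
63 3 75.1000 62.0000 0 1.0000 5
64 3 75.1000 63.0000 0 1.0000 5
65 3 75.1000 64.0000 0 1.0000 5
66 3 75.1000 65.0000 0 1.0000 5
67 3 75.1000 66.0000 0 1.0000 5
68 3 75.1000 67.0000 0 1.0000 5
69 3 75.1000 68.0000 0 1.0000 5
70 3 75.1000 69.0000 0 1.0000 5
71 3 75.1000 70.0000 0 1.0000 5
72 3 75.1000 71.0000 0 1.0000 5
73 3 75.1000 72.0000 0 1.0000 5
74 3 75.1000 73.0000 0 1.0000 5
75 3 75.1000 74.0000 0 1.0000 5
76 3 75.1000 75.0000 0 1.0000 5
77 3 75.1000 76.0000 0 1.0000 5
78 3 72.3000 77.0000 0 1.0000 6
79 3 72.3000 78.0000 0 1.0000 6
80 3 72.3000 79.0000 0 1.0000 6
81 3 72.3000 80.0000 0 1.0000 6
82 3 72.3000 81.0000 0 1.0000 6
83 3 72.3000 82.0000 0 1.0000 6
84 3 72.3000 83.0000 0 1.0000 6
85 3 72.3000 84.0000 0 1.0000 6
86 3 72.3000 85.0000 0 1.0000 6
87 3 72.3000 86.0000 0 1.0000 6
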