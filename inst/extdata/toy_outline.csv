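"x","y"
4,0
3.98074,0.39207
3.92314,0.78036
3.82776,1.16114
3.69552,1.53073
3.52769,1.88559
3.32588,2.22228
3.09204,2.53757
2.82843,2.82843
2.53757,3.09204
2.22228,3.32588
1.88559,3.52769
1.53073,3.69552
1.16114,3.82776
0.78036,3.92314
0.39207,3.98074
0,4
-0.39207,3.98074
-0.78036,3.92314
-1.16114,3.82776
-1.53073,3.69552
-1.88559,3.52769
-2.22228,3.32588
-2.53757,3.09204
-2.82843,2.82843
-3.09204,2.53757
-3.32588,2.22228
-3.52769,1.88559
-3.69552,1.53073
-3.82776,1.16114
-3.92314,0.78036
-3.98074,0.39207
-4,0
-3.98074,-0.39207
-3.92314,-0.78036
-3.82776,-1.16114
-3.69552,-1.53073
-3.52769,-1.88559
-3.32588,-2.22228
-3.09204,-2.53757
-2.82843,-2.82843
-2.53757,-3.09204
-2.22228,-3.32588
-1.88559,-3.52769
-1.53073,-3.69552
-1.16114,-3.82776
-0.78036,-3.92314
-0.39207,-3.98074
0,-4
0.39207,-3.98074
0.78036,-3.92314
1.16114,-3.82776
1.53073,-3.69552
1.88559,-3.52769
2.22228,-3.32588
2.53757,-3.09204
2.82843,-2.82843
3.09204,-2.53757
3.32588,-2.22228
3.52769,-1.88559
3.69552,-1.53073
3.82776,-1.16114
3.92314,-0.78036
3.98074,-0.39207
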