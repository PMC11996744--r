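ply
format ascii 1.0
element vertex 4
property double x
property double y
property double z
element face 4
property list uchar int vertex_indices
end_header
0.35355339059327373 0.35355339059327373 0.35355339059327373
0.35355339059327373 -0.35355339059327373 -0.35355339059327373
-0.35355339059327373 0.35355339059327373 -0.35355339059327373
-0.35355339059327373 -0.35355339059327373 0.35355339059327373
3 0 2 1
3 0 1 3
3 0 3 2
3 1 2 3
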