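hospital_id,C_i,rank
H1,0.6436,2
H2,0.6752,1
H3,0.6369,3
H4,0.6257,4
H5,0.4945,9
H6,0.4261,14
H7,0.5101,7
H8,0.4923,10
H9,0.4913,11
H10,0.4804,12
H11,0.4996,8
H12,0.5551,6
H13,0.4621,13
H14,0.5855,5
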