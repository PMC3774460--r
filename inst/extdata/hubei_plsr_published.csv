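hospital_id,observed,predicted
H1,0.6436,0.6377
H2,0.6752,0.6242
H3,0.6369,0.6225
H4,0.6257,0.5879
H5,0.4945,0.5405
H6,0.4261,0.4526
H7,0.5101,0.5374
H8,0.4923,0.5429
H9,0.4913,0.4674
H10,0.4804,0.5051
H11,0.4996,0.5619
H12,0.5551,0.5217
H13,0.4621,0.4817
H14,0.5855,0.6410
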