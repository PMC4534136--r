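P3
# tiny synthetic 4x3 test card
4 3
255
255 0 0  0 255 0  0 0 255  255 255 255
0 0 0  128 128 128  255 128 0  64 64 192
10 20 30  200 100 50  0 128 128  255 255 0
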