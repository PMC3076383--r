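name	handedness	polynomial
U	achiral	1
3_1	R	1*l^-2*m^2 - 2*l^-2 - 1*l^-4
3_1	L	-1*l^4 + 1*l^2*m^2 - 2*l^2
4_1	achiral	-1*l^2 + 1*m^2 - 1 - 1*l^-2
5_1	R	1*l^-4*m^4 - 4*l^-4*m^2 + 3*l^-4 - 1*l^-6*m^2 + 2*l^-6
5_1	L	-1*l^6*m^2 + 2*l^6 + 1*l^4*m^4 - 4*l^4*m^2 + 3*l^4
5_2	R	1*l^-2*m^2 - 1*l^-2 - 1*l^-4*m^2 + 1*l^-4 + 1*l^-6
5_2	L	1*l^6 - 1*l^4*m^2 + 1*l^4 + 1*l^2*m^2 - 1*l^2
6_1	R	-1*l^2 + 1*m^2 - 1*l^-2*m^2 + 1*l^-2 + 1*l^-4
6_1	L	1*l^4 - 1*l^2*m^2 + 1*l^2 + 1*m^2 - 1*l^-2
Hopf+	n/a	-1*l^-1*m^1 + 1*l^-1*m^-1 + 1*l^-3*m^-1
Hopf-	n/a	1*l^3*m^-1 - 1*l^1*m^1 + 1*l^1*m^-1
unlink_2	n/a	-1*l^1*m^-1 - 1*l^-1*m^-1
unlink_3	n/a	1*l^2*m^-2 + 2*m^-2 + 1*l^-2*m^-2
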