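# Calibrated resting state of the six-compartment electrodiffusive model
# Internal units: amounts amol, gates dimensionless, volumes um^3
# relative drift: 4.378e-11 per ms
# phi_msn -75.0727 mV, phi_msg -82.1461 mV
name	value
Na_sn	2.6476452883568672e+04
Na_se	8.6481446823433696e+04
Na_sg	2.0152226800273766e+04
Na_dn	2.6539525990023063e+04
Na_de	8.6722189416398105e+04
Na_dg	2.0114558086302612e+04
K_sn	1.3836491562729201e+05
K_se	2.1908052246695738e+03
K_sg	1.4605439833683136e+05
K_dn	1.3817682268962637e+05
K_de	2.3040775751745355e+03
K_dg	1.4609098054640595e+05
Cl_sn	9.6465401442126768e+03
Cl_se	7.9525176026485351e+04
Cl_sg	8.7113160606780475e+03
Cl_dn	9.5216202629015243e+03
Cl_de	7.9881116799358730e+04
Cl_dg	8.7102307063635708e+03
Ca_sn	1.4249727467768938e+01
Ca_se	6.4863299278892543e+02
Ca_dn	1.4248180326672086e+01
Ca_de	6.4960909941663363e+02
n	5.8600484869164257e-05
h	9.9991341925503729e-01
s	3.5924684866302037e-03
c	2.5683034210839690e-03
q	3.4280937391183169e-01
z	9.9999977458474432e-01
V_sn	1.4249805338899539e+03
V_se	6.0110623453553035e+02
V_sg	1.4379132315745169e+03
V_dn	1.4235185738641587e+03
V_de	6.0321014753937550e+02
V_dg	1.4372712785964652e+03
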