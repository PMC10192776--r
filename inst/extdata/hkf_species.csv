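name,formula,charge,dG_f_ref_kJ,S_ref_J,a1,a2,a3,a4,c1,c2,omega,citation
oxalate,C:2;O:4,-2,-673.900,45.606,7.8152,0,0,0,-5.855,-16.1732,3.0509,"G/S: NBS tables (Wagman et al. 1982; consistent with oxalic-acid pKa2); Cp -270 J/(mol K) and V 25 cm3/mol estimated from divalent-oxyanion systematics (bracketed by SO4-2 and CO3-2); c1/c2/omega/a1 derived via Shock & Helgeson (1988) correlations"
formate,C:1;H:1;O:2,-1,-350.879,90.793,7.0405,0,0,0,4.901,-7.3123,1.3068,"G/S/Cp/V: Shock & Helgeson (1990); c1/c2/omega/a1 derived via Shock & Helgeson (1988) correlations"
bicarbonate,C:1;H:1;O:3,-1,-586.940,98.450,7.5621,1.1505,1.2346,-2.8266,12.9395,-4.7579,1.2733,"Shock & Helgeson (1988) regressed HKF set (SUPCRT slop lineage)"
sulfate,S:1;O:4,-2,-744.459,18.828,8.3014,-1.9846,-6.2122,-2.6970,1.64,-17.998,3.1463,"Shock & Helgeson (1988) regressed HKF set (SUPCRT slop lineage)"
methane,C:1;H:4,0,-34.451,87.822,6.7621,11.6342,3.1561,-3.9675,40.87,8.8004,-0.3179,"CH4(aq), Shock & Helgeson (1990) regressed HKF set (SUPCRT slop lineage)"
bisulfide,H:1;S:1,-1,11.966,68.199,5.0119,4.9799,3.4765,-2.9849,3.42,-6.27,1.4410,"HS-, Shock & Helgeson (1988) regressed HKF set (SUPCRT slop lineage)"
water,H:2;O:1,0,-237.183,69.950,NA,NA,NA,NA,NA,NA,NA,"liquid water; reference value SUPCRT lineage; T-P dependence from the package water model (Kell 1975 density, Bradley-Pitzer 1979 dielectric, calorimetric Cp)"
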