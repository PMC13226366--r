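stratifier,stratum,year,share
overall,all,2022,1.000
overall,all,2030,1.000
overall,all,2040,1.000
age_group,65-74,2022,0.570
age_group,65-74,2030,0.516
age_group,65-74,2040,0.417
age_group,75-84,2022,0.311
age_group,75-84,2030,0.355
age_group,75-84,2040,0.390
age_group,85+,2022,0.119
age_group,85+,2030,0.129
age_group,85+,2040,0.193
sex,men,2022,0.450
sex,men,2030,0.452
sex,men,2040,0.450
sex,women,2022,0.550
sex,women,2030,0.548
sex,women,2040,0.550
race,White,2022,0.887
race,White,2030,0.874
race,White,2040,0.856
race,Black,2022,0.113
race,Black,2030,0.126
race,Black,2040,0.144
family_structure,U0,2022,0.050
family_structure,U0,2030,0.058
family_structure,U0,2040,0.062
family_structure,UB,2022,0.207
family_structure,UB,2030,0.193
family_structure,UB,2040,0.194
family_structure,US,2022,0.163
family_structure,US,2030,0.159
family_structure,US,2040,0.166
family_structure,M0,2022,0.051
family_structure,M0,2030,0.062
family_structure,M0,2040,0.056
family_structure,MB,2022,0.293
family_structure,MB,2030,0.291
family_structure,MB,2040,0.286
family_structure,MS,2022,0.237
family_structure,MS,2030,0.238
family_structure,MS,2040,0.235
family_size,0,2022,0.050
family_size,0,2030,0.058
family_size,0,2040,0.062
family_size,1,2022,0.100
family_size,1,2030,0.117
family_size,1,2040,0.117
family_size,2,2022,0.154
family_size,2,2030,0.158
family_size,2,2040,0.158
family_size,3,2022,0.197
family_size,3,2030,0.194
family_size,3,2040,0.190
family_size,4+,2022,0.498
family_size,4+,2030,0.474
family_size,4+,2040,0.473
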