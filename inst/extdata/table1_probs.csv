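stratifier,stratum,outcome,probability
overall,all,no_family_caregiver,0.110
overall,all,no_caregivers,0.097
overall,all,paid_only,0.013
overall,all,unmet_need,0.151
age_group,65-74,no_family_caregiver,0.094
age_group,65-74,no_caregivers,0.083
age_group,65-74,paid_only,0.011
age_group,65-74,unmet_need,0.132
age_group,75-84,no_family_caregiver,0.129
age_group,75-84,no_caregivers,0.121
age_group,75-84,paid_only,0.008
age_group,75-84,unmet_need,0.160
age_group,85+,no_family_caregiver,0.133
age_group,85+,no_caregivers,0.093
age_group,85+,paid_only,0.040
age_group,85+,unmet_need,0.227
sex,men,no_family_caregiver,0.111
sex,men,no_caregivers,0.098
sex,men,paid_only,0.013
sex,men,unmet_need,0.128
sex,women,no_family_caregiver,0.109
sex,women,no_caregivers,0.096
sex,women,paid_only,0.013
sex,women,unmet_need,0.170
race,White,no_family_caregiver,0.109
race,White,no_caregivers,0.097
race,White,paid_only,0.012
race,White,unmet_need,0.147
race,Black,no_family_caregiver,0.116
race,Black,no_caregivers,0.096
race,Black,paid_only,0.020
race,Black,unmet_need,0.187
family_structure,U0,no_family_caregiver,0.173
family_structure,U0,no_caregivers,0.133
family_structure,U0,paid_only,0.040
family_structure,U0,unmet_need,0.202
family_structure,UB,no_family_caregiver,0.128
family_structure,UB,no_caregivers,0.105
family_structure,UB,paid_only,0.023
family_structure,UB,unmet_need,0.215
family_structure,US,no_family_caregiver,0.145
family_structure,US,no_caregivers,0.105
family_structure,US,paid_only,0.040
family_structure,US,unmet_need,0.192
family_structure,M0,no_family_caregiver,0.109
family_structure,M0,no_caregivers,0.109
family_structure,M0,paid_only,0.000
family_structure,M0,unmet_need,0.088
family_structure,MB,no_family_caregiver,0.076
family_structure,MB,no_caregivers,0.074
family_structure,MB,paid_only,0.002
family_structure,MB,unmet_need,0.102
family_structure,MS,no_family_caregiver,0.103
family_structure,MS,no_caregivers,0.102
family_structure,MS,paid_only,0.001
family_structure,MS,unmet_need,0.133
family_size,0,no_family_caregiver,0.173
family_size,0,no_caregivers,0.133
family_size,0,paid_only,0.040
family_size,0,unmet_need,0.202
family_size,1,no_family_caregiver,0.101
family_size,1,no_caregivers,0.097
family_size,1,paid_only,0.004
family_size,1,unmet_need,0.154
family_size,2,no_family_caregiver,0.130
family_size,2,no_caregivers,0.110
family_size,2,paid_only,0.020
family_size,2,unmet_need,0.172
family_size,3,no_family_caregiver,0.084
family_size,3,no_caregivers,0.076
family_size,3,paid_only,0.008
family_size,3,unmet_need,0.127
family_size,4+,no_family_caregiver,0.109
family_size,4+,no_caregivers,0.097
family_size,4+,paid_only,0.012
family_size,4+,unmet_need,0.149
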