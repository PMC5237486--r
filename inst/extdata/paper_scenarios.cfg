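[scenario:base]
supply.population_base = 4307710
supply.births_per_donor = 25
supply.stage.awareness = 25% | proportion of men aware of program
supply.stage.willingness = 15% | proportion of men willing to donate
supply.stage.presenting = 3% | proportion of men presenting for screening
supply.stage.medical_pass = 0.013 | medical screening pass rate, decimal encoding
segment.same_sex_couples.base_count = 29380
segment.same_sex_couples.seeking.wishing_children = 15% | same-sex couples wishing to have children
segment.same_sex_couples.recipient_eligibility = 98% | couples meeting screening criteria
segment.single_women.base_population = 5567965
segment.single_women.base.single_fraction = 39.3% | proportion of women 20-44 who are single
segment.single_women.seeking.seeking_donation = 0.06% | single women seeking sperm donation
segment.single_women.recipient_eligibility = 98% | women meeting screening criteria
segment.heterosexual_couples.base_count = 3335815
segment.heterosexual_couples.seeking.infertility = 16% | couples experiencing fertility issues
segment.heterosexual_couples.seeking.male_factor = 24.0% | infertility attributed to the male partner (prose elsewhere says 30%; only 24.0% reproduces the published demand)
segment.heterosexual_couples.seeking.seeking_donation = 1.8% | couples seeking donor insemination
segment.heterosexual_couples.recipient_eligibility = 98.0% | couples meeting screening criteria

[scenario:best]
supply.population_base = 4307710
supply.births_per_donor = 25
supply.stage.awareness = 55% | proportion of men aware of program
supply.stage.willingness = 50% | proportion of men willing to donate
supply.stage.presenting = 25% | proportion of men presenting for screening
supply.stage.medical_pass = 1/78 | medical screening pass rate, 1/78 rational encoding
segment.same_sex_couples.base_count = 29380
segment.same_sex_couples.seeking.wishing_children = 15% | same-sex couples wishing to have children
segment.same_sex_couples.recipient_eligibility = 98% | couples meeting screening criteria
segment.single_women.base_population = 5567965
segment.single_women.base.single_fraction = 39.3% | proportion of women 20-44 who are single
segment.single_women.seeking.seeking_donation = 0.06% | single women seeking sperm donation
segment.single_women.recipient_eligibility = 98% | women meeting screening criteria
segment.heterosexual_couples.base_count = 3335815
segment.heterosexual_couples.seeking.infertility = 16% | couples experiencing fertility issues
segment.heterosexual_couples.seeking.male_factor = 24.0% | infertility attributed to the male partner (prose elsewhere says 30%; only 24.0% reproduces the published demand)
segment.heterosexual_couples.seeking.seeking_donation = 1.8% | couples seeking donor insemination
segment.heterosexual_couples.recipient_eligibility = 98.0% | couples meeting screening criteria

[scenario:worst]
supply.population_base = 4307710
supply.births_per_donor = 25
supply.stage.awareness = 25% | proportion of men aware of program
supply.stage.willingness = 15% | proportion of men willing to donate
supply.stage.presenting = 3% | proportion of men presenting for screening
supply.stage.medical_pass = 0.013 | medical screening pass rate, decimal encoding
segment.same_sex_couples.base_count = 29380
segment.same_sex_couples.seeking.wishing_children = 25% | same-sex couples wishing to have children
segment.same_sex_couples.recipient_eligibility = 98% | couples meeting screening criteria
segment.single_women.base_population = 5567965
segment.single_women.base.single_fraction = 39.3% | proportion of women 20-44 who are single
segment.single_women.seeking.seeking_donation = 1% | single women seeking sperm donation
segment.single_women.recipient_eligibility = 98% | women meeting screening criteria
segment.heterosexual_couples.base_count = 3335815
segment.heterosexual_couples.seeking.infertility = 16% | couples experiencing fertility issues
segment.heterosexual_couples.seeking.male_factor = 24.0% | infertility attributed to the male partner (prose elsewhere says 30%; only 24.0% reproduces the published demand)
segment.heterosexual_couples.seeking.seeking_donation = 3% | couples seeking donor insemination
segment.heterosexual_couples.recipient_eligibility = 98.0% | couples meeting screening criteria
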