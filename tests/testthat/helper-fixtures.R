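# shared fixtures: one parameter set and reference diet reused across files
test_params <- default_params()
test_diet <- default_diet(test_params)
test_yields <- coupling_yields(test_diet, test_params$compounds$reserve,
                               test_params$sigma_A)

# short Fig-6-style scenario builder (group of fish, single diet)
fig6_scenario <- function(duration = 30, ration = 0.012, meals = 1,
                          temp = 15, weight = 150, n_fish = 100,
                          diet = test_diet) {
  scenario(duration = duration, initial_weight = weight, temperature = temp,
           schedule = feeding_schedule(duration, meals, ration),
           diets = list(diet = diet), n_fish = n_fish)
}
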