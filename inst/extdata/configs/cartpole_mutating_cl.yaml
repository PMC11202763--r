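# Counterfactual learner on the mutating cart-pole: thresholds halve
# after episode 100.
agent:
  type: cl
env:
  type: cartpole
  step_budget: 200
n_episodes: 140
n_seeds: 20
seed: 101
mutations:
  - episode: 100
    env:
      type: cartpole
      angle_limit_deg: 6
      position_limit: 1.2
      step_budget: 200
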