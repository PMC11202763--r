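# Mixed agent (planning depth 25) on the mutating grid: easy variant
# (optimal path 4) for 35 episodes, then the hard variant (optimal 14).
agent:
  type: mixed
  horizon: 25
  alpha_norm: 0.1
  efe_precision: 1
env:
  type: grid
  maze_file: ../mazes/mutating_easy_synthetic.txt
  step_budget: 1500
n_episodes: 80
n_seeds: 20
seed: 202
mutations:
  - episode: 35
    env:
      type: grid
      maze_file: ../mazes/mutating_hard_synthetic.txt
      step_budget: 1500
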