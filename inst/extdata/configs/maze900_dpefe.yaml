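# Planner on the 900-state maze (synthetic stand-in, optimal path 47).
agent:
  type: dpefe
  horizon: 25
  alpha: 1
env:
  type: grid
  maze_file: ../mazes/maze30_synthetic.txt
  step_budget: 30000
n_episodes: 15
n_seeds: 5
seed: 11
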