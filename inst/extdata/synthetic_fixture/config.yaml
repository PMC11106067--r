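# Synthetic demonstration analysis: six Northern-Hemisphere regions,
# three land-bridge epochs (>30, 30-5, 5-0 Ma).
areas: [WNA, ENA, JP, EU, EA, CA]
adjacent:
  - [WNA, ENA]
  - [EA, JP]
  - [EA, CA]
  - [JP, CA]
  - [EU, CA]
tree: tree.nwk
tip_ranges: tip_ranges.tsv
temperature: temperature.csv
max_range_size: 6
epochs:
  boundaries: [30, 5]
  multipliers:
    # oldest epoch, > 30 Ma: both land bridges fully open
    - pairs:
        WNA-ENA: 1
        WNA-JP: 1
        WNA-EU: 1
        WNA-EA: 1
        WNA-CA: 1
        ENA-JP: 1
        ENA-EU: 1
        ENA-EA: 1
        ENA-CA: 1
        JP-EU: 1
        JP-EA: 1
        JP-CA: 1
        EU-EA: 1
        EU-CA: 1
        EA-CA: 1
    # 30-5 Ma: North Atlantic bridge weakened
    - pairs:
        WNA-ENA: 1
        WNA-JP: 1
        WNA-EU: 0.5
        WNA-EA: 1
        WNA-CA: 1
        ENA-JP: 1
        ENA-EU: 1
        ENA-EA: 1
        ENA-CA: 1
        JP-EU: 1
        JP-EA: 1
        JP-CA: 1
        EU-EA: 1
        EU-CA: 1
        EA-CA: 1
    # 5-0 Ma: North Atlantic bridge nearly severed, Bering bridge weaker
    - pairs:
        WNA-ENA: 1
        WNA-JP: 1
        WNA-EU: 1
        WNA-EA: 0.5
        WNA-CA: 1
        ENA-JP: 1
        ENA-EU: 0.25
        ENA-EA: 1
        ENA-CA: 1
        JP-EU: 1
        JP-EA: 1
        JP-CA: 1
        EU-EA: 1
        EU-CA: 1
        EA-CA: 1
models: [DEC, DEC+J]
root_prior: uniform
density_bandwidth: 1.5
grid_step: 0.25
loess_span: 0.25
slope_delta: 0.1
period_boundaries: [30, 15, 5]
period_labels: [Warm I, Cold I, Warm II, Cold II]
n_starts: 2
seed: 1
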