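# Reference parameter files

- `predation_params.json` — base scenario of the population-size,
  attack-intensity and escape-cost experiments (`reference_params("predation")`).
- `coexistence_params.json` — background-fitness scenario
  (`reference_params("coexistence")`).

These are the package's reference study conditions: chosen once to exhibit
the model's characteristic regimes (see the methods vignette) and then
fixed.  They are modelling choices, not field measurements; treat them as
a starting point and adjust to your own system.
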