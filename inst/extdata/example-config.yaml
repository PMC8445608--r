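# Example configuration for inst/scripts/dcis-cli.R
# Any simConfig() parameter may appear here; unset values keep the
# literature-baseline defaults (print them with the `defaults` command).
luminalDiameter: 100     # um; 100, 150 or 200 at baseline
axialLength: 1000        # um duct section
days: 12
nTics: 5
thresholdsEnabled: false # baseline growth protocol
seed: 1
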