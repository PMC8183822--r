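# Minimal end-to-end run at desk scale; see ?runPipeline
nLines: 60
nMarkers: 400
nEnvs: 4
seed: 11
mcmcProfile: test
tpSize: 20
nPartitions: 5
seModels: [GB, BayesA]
meModels: [MM, MDe]
outDir: magicGP-run
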