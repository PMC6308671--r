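# Bundled demo: two-instrument simulation, feature selection and
# decision-level fusion at desk scale (runs in about a minute on 1 CPU).
seed = 42
n_healthy = 60
n_bruised = 60
n_healthy_pred = 40
n_bruised_pred = 48
rho = 0.5
effect_size = 0.12
noise_sd = 0.01
scatter_sd = 0.05
bands_pb = 24
bands_lctf = 28
classifier = plsda
folds = 5
frog_iter = 40
max_features = 10
level = decision
decision_rule = all
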