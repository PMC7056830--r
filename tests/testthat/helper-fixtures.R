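# shared fixtures, built in code

zero_frame <- function(t = 0) tactile_frame(numeric(288), t = t)

random_frame <- function(seed = 1, t = 0) {
  set.seed(seed)
  tactile_frame(runif(288), t = t)
}

constant_stream <- function(value = 0.5, n = 10, fs = 100) {
  tactile_stream(time = (seq_len(n) - 1) / fs,
                 values = matrix(value, nrow = n, ncol = 288), fs = fs)
}

random_stream <- function(seed = 1, n = 20, fs = 100) {
  set.seed(seed)
  tactile_stream(time = (seq_len(n) - 1) / fs,
                 values = matrix(runif(n * 288), nrow = n), fs = fs)
}

# small noiseless simulator setup shared across tests
ideal_sensor <- function(seed = 1, ...) {
  sensor_model(noise_sd = 0, drift_rate = 0, response = "linear",
               seed = seed, ...)
}

quick_protocol <- function(...) {
  training_protocol(rest_s = 0.5, ramp_s = 0.3, plateau_s = 0.8, ...)
}

default_targets <- function(limits = activation_limits()) {
  lapply(default_task_config(limits),
         function(tk) target_spec(tk$name, tk$activations, tk$group))
}
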