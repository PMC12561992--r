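## Shared, lazily-computed objects so expensive network simulations are run
## once per test session.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

default_net <- function() cached("net", fen_network())
default_sch <- function() cached("sch", fen_glucose())
disease_traj <- function() {
  cached("traj_d", simulate_network(default_net(), default_sch(),
                                    structure = fenestration_params()))
}
healthy_traj <- function() {
  cached("traj_h",
         simulate_network(network_variant(default_net(), "healthy"),
                          default_sch()))
}
noiseless_study <- function() {
  cached("study0", synthetic_study(seed = 11, sd_density = 0,
                                   sd_width_nm = 0))
}
noiseless_fit <- function() {
  s <- noiseless_study()
  cached("fit0", fit_fenestration(s$obs, net = s$net,
                                  schedule = s$schedule, seed = 11))
}

## A constant-weight glucose schedule: linear segment degenerate at g0,
## then intervals at g0 + w * span so the normalized weight is w from
## 1008 h on.
held_weight_schedule <- function(w, g0 = 10, span = 20) {
  iv <- data.frame(t_start_h = 1008, t_end_h = 6000,
                   mean_mmol_l = g0 + w * span, sd_mmol_l = 0)
  glucose_schedule(iv, slope = 0, intercept = g0, gmax = g0 + span)
}

## Tiny 4-node toy network exercising weights, inhibition and an AND gate.
toy_network <- function() {
  species <- data.frame(
    id = c("A", "B", "C", "D"),
    ymax = c(1, 1, 0.9, 1), y0 = 0,
    tau_class = c("custom", "signaling", "signaling", "signaling"),
    tau = c(1, NA, NA, NA), compartment = "GEC")
  reactions <- data.frame(
    id = 1:4,
    rule = c("A => B", "!A => C", "A & B => D", "C => D"),
    W = c(0.8, 0.9, 1, 0.7), n = 1.4, EC50 = c(0.5, 0.5, 0.4, 0.6))
  network_spec(species, reactions, stimulus = "A")
}
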